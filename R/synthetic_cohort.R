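# Deterministic sub-seed derivation so one config seed drives several
# independent draws (expression, survival, gene sets) without reuse.
# Keeps results inside 32-bit integer range.
.derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + 12345 * stream) %% 2147483647)
}

#' Configuration for a synthetic anchor-ratio survival cohort
#'
#' Describes a simulated bulk RNA-Seq study: a cohort of subjects, a feature
#' panel containing one anchor gene, optional "effect" features whose
#' anchor/gene ratio group carries a known hazard effect, and a fully
#' seeding RNG policy. The defaults emulate the design of the real study
#' this package's screen is modeled on: 189 stage-IIIC subjects followed to
#' a 3650-day (10-year) horizon.
#'
#' @param n_subjects cohort size (>= 20). Default 189.
#' @param n_features number of expression features including the anchor.
#' @param anchor_feature_id anchor gene ID. Default `"OPCML"`.
#' @param effect_feature_ids features whose high-ratio group receives the
#'   hazard effect; must be features other than the anchor. Default none
#'   (an all-null cohort).
#' @param true_log_hazard log hazard ratio of the high-ratio group relative
#'   to the low-ratio group for each effect feature (scalar, recycled, or
#'   one value per effect feature). Default `log(2)`.
#' @param baseline_hazard baseline event hazard per day. The default 1/1000
#'   puts median survival near 2 years, typical of advanced serous ovarian
#'   cancer, and leaves only a few percent of subjects alive at the
#'   10-year horizon.
#' @param censor_horizon administrative censoring horizon in days.
#' @param noise_model `"log-normal"` (default) or `"negative-binomial"`
#'   subject-level noise on the normalized-count scale.
#' @param seed integer seed; fully determines all generated outputs.
#' @return a `simulation_config` list; `feature_ids(config)` lists the full
#'   feature panel (`anchor`, then `G00001`, `G00002`, ...).
#' @export
simulation_config <- function(n_subjects = 189L,
                              n_features = 2000L,
                              anchor_feature_id = "OPCML",
                              effect_feature_ids = character(),
                              true_log_hazard = log(2),
                              baseline_hazard = 1 / 1000,
                              censor_horizon = 3650L,
                              noise_model = c("log-normal", "negative-binomial"),
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_subjects < 20L) stop("n_subjects must be >= 20", call. = FALSE)
  if (n_features < 2L) stop("need the anchor plus at least one feature", call. = FALSE)
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_features = as.integer(n_features),
      anchor_feature_id = anchor_feature_id,
      effect_feature_ids = as.character(effect_feature_ids),
      true_log_hazard = true_log_hazard,
      baseline_hazard = baseline_hazard,
      censor_horizon = as.integer(censor_horizon),
      noise_model = noise_model,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
  ids <- feature_ids(cfg)
  if (anchor_feature_id %in% cfg$effect_feature_ids) {
    stop("the anchor cannot be an effect feature", call. = FALSE)
  }
  if (!all(cfg$effect_feature_ids %in% ids)) {
    stop("effect_feature_ids must belong to the feature panel", call. = FALSE)
  }
  n_eff <- length(cfg$effect_feature_ids)
  if (n_eff > 0L) {
    cfg$true_log_hazard <- rep_len(true_log_hazard, n_eff)
  }
  cfg
}

#' @rdname simulation_config
#' @param config a `simulation_config`.
#' @export
feature_ids <- function(config) {
  c(
    config$anchor_feature_id,
    sprintf("G%05d", seq_len(config$n_features - 1L))
  )
}

#' Generate a synthetic normalized expression matrix
#'
#' Each feature gets its own baseline abundance (log-normal across features,
#' spanning roughly two orders of magnitude) and independent subject-level
#' noise — log-normal or negative-binomial per the config. Features are
#' pairwise independent and carry no survival information by construction;
#' hazard effects are attached later by [generate_survival()].
#'
#' @param config a [simulation_config()].
#' @return an [expression_matrix()] in the `normalized` state,
#'   `n_features` x `n_subjects`.
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- feature_ids(config)
  nf <- config$n_features
  ns <- config$n_subjects
  values <- withr::with_seed(.derive_seed(config$seed, 1L), {
    meanlog <- stats::rnorm(nf, mean = log(500), sd = 1.5)
    if (config$noise_model == "log-normal") {
      matrix(stats::rlnorm(nf * ns, meanlog = meanlog, sdlog = 0.8),
        nrow = nf, ncol = ns
      )
    } else {
      matrix(stats::rnbinom(nf * ns, mu = exp(meanlog), size = 2),
        nrow = nf, ncol = ns
      ) * 1.0
    }
  })
  rownames(values) <- ids
  colnames(values) <- sprintf("S%04d", seq_len(ns))
  expression_matrix(values, transform = "normalized")
}

#' Generate survival outcomes with ratio-linked hazard effects
#'
#' Event times are exponential with per-subject hazard
#' `baseline_hazard * exp(sum_j theta_j * I(subject in the high anchor/gene
#' ratio half for effect feature j))`. The high/low split is the same
#' median dichotomization of the log2(x+4) anchor/gene ratio that the screen
#' estimates, so `exp(theta_j)` IS the true group hazard ratio (high vs low)
#' the downstream Cox fit should recover. Null features contribute nothing.
#' Times are rounded up to integer days; subjects surviving past the
#' horizon are censored there.
#'
#' @param config a [simulation_config()].
#' @param expr the matching [generate_expression()] output (normalized
#'   state), containing the anchor and every effect feature.
#' @return a [clinical_cohort()] with one row per expression column.
#' @export
generate_survival <- function(config, expr) {
  stopifnot(inherits(config, "simulation_config"), inherits(expr, "expr_matrix"))
  if (!config$anchor_feature_id %in% rownames(expr)) {
    stop("anchor feature missing from expression matrix", call. = FALSE)
  }
  if (!all(config$effect_feature_ids %in% rownames(expr))) {
    stop("effect feature(s) missing from expression matrix", call. = FALSE)
  }
  ns <- ncol(expr)
  lp <- rep(0, ns)
  if (length(config$effect_feature_ids) > 0L) {
    lg <- log2p4_transform(expr)
    anchor_v <- lg[config$anchor_feature_id, ]
    for (j in seq_along(config$effect_feature_ids)) {
      ratio <- anchor_v / lg[config$effect_feature_ids[j], ]
      high <- ratio > stats::median(ratio)
      lp <- lp + config$true_log_hazard[j] * high
    }
  }
  rate <- config$baseline_hazard * exp(lp)
  t_raw <- withr::with_seed(
    .derive_seed(config$seed, 2L),
    stats::rexp(ns, rate = 1) / rate
  )
  days <- pmax(1L, as.integer(ceiling(t_raw)))
  censored <- days >= config$censor_horizon
  days[censored] <- config$censor_horizon
  clinical_cohort(
    subject_id = colnames(expr),
    days_to_death = days,
    event = !censored,
    stage = "IIIC"
  )
}

#' Generate gene-set collections with a planted enriched set
#'
#' Builds `n_sets` random gene sets over the non-anchor feature universe.
#' When the config declares effect features and `n_sets >= 1`, the first
#' set (`"PLANTED_SET"`) is deliberately enriched for them: it has the same
#' size as the effect panel and a fraction `planted_overlap` of its members
#' are effect features (at `planted_overlap = 1` it is exactly the effect
#' panel). Remaining sets are uniform draws.
#'
#' @param config a [simulation_config()].
#' @param n_sets number of sets (0 gives an empty, still GMT-writable
#'   collection).
#' @param set_size_range inclusive size range for the random sets.
#' @param planted_overlap fraction of the planted set drawn from the effect
#'   features.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(config, n_sets = 10L,
                               set_size_range = c(5L, 25L),
                               planted_overlap = 1.0) {
  stopifnot(inherits(config, "simulation_config"))
  universe <- setdiff(feature_ids(config), config$anchor_feature_id)
  if (max(set_size_range) > length(universe)) {
    stop("set size exceeds the feature universe", call. = FALSE)
  }
  if (n_sets == 0L) {
    return(gene_set_collection(stats::setNames(list(), character()), universe))
  }
  eff <- config$effect_feature_ids
  withr::with_seed(.derive_seed(config$seed, 3L), {
    sets <- list()
    if (length(eff) > 0L) {
      k <- round(planted_overlap * length(eff))
      filler <- sample(setdiff(universe, eff), length(eff) - k)
      sets[["PLANTED_SET"]] <- c(sample(eff, k), filler)
    }
    while (length(sets) < n_sets) {
      nm <- sprintf("RANDOM_SET_%03d", length(sets) + 1L)
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
      sets[[nm]] <- sample(universe, size)
    }
    gene_set_collection(
      sets, universe,
      descriptions = ifelse(names(sets) == "PLANTED_SET",
        "planted effect-feature set", "random set"
      )
    )
  })
}

#' Synthetic per-gene citation counts
#'
#' Offline stand-in for a literature count table: counts are drawn from a
#' heavy-tailed (log-normal, rounded) distribution resembling real PubMed
#' per-gene citation counts. Purely a fixture generator; it is labelled
#' synthetic and never mimics any real gene's count.
#'
#' @param genes character vector of gene IDs.
#' @param seed integer seed.
#' @return a data.frame `gene_id`, `count` usable as a citation table.
#' @export
synthetic_citation_counts <- function(genes, seed = 1L) {
  counts <- withr::with_seed(
    .derive_seed(seed, 4L),
    as.integer(round(stats::rlnorm(length(genes), meanlog = 1.5, sdlog = 1.5)))
  )
  data.frame(gene_id = as.character(genes), count = counts,
             stringsAsFactors = FALSE)
}
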