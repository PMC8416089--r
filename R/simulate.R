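#' Configuration for a synthetic two-group proteomics cohort
#'
#' Describes a log-normal abundance model with planted group effects and
#' abundance-dependent detection dropout. Per protein `p` and sample `s`:
#'
#' `log2 abundance(p, s) = baseline_p + effect_p * [s is case] + noise`,
#'
#' with `baseline_p ~ N(baseline_mean, baseline_sd)`, Gaussian noise of SD
#' `noise_sd`, and each measurement retained with probability
#' `plogis(dropout_slope * log2abundance + dropout_intercept)` (zeroed
#' otherwise). Low-abundance proteins therefore drop out preferentially,
#' which — combined with a planted effect — produces group-exclusive
#' detection near the detection limit. An additional `exclusive_rate`
#' fraction of proteins is zeroed wholesale in one random group,
#' emulating strictly on/off proteins.
#'
#' Defaults model a desk-scale label-free cohort: 1,000 proteins, 20 vs
#' 20 samples, 80 up- and 40 down-regulated proteins at a log2 effect of
#' 2, within-group noise SD 1 (roughly a 2-fold CV), and a sharp
#' detection limit centred ~16-fold below the median protein
#' (`plogis(2 * x - 12)`), yielding ~12% missing measurements
#' concentrated in low-abundance proteins, as in real label-free data.
#'
#' @param n_proteins,n_case,n_control Cohort dimensions.
#' @param baseline_mean,baseline_sd Log2-scale between-protein abundance
#'   distribution.
#' @param noise_sd Within-group log2 measurement noise SD.
#' @param n_up,n_down Numbers of planted up/down proteins.
#' @param effect_size Planted |log2 effect|.
#' @param dropout_slope,dropout_intercept Logistic detection model in
#'   log2 abundance (`slope = 0, intercept = Inf` disables dropout).
#' @param exclusive_rate Fraction of proteins forced to zero in one
#'   random group.
#' @param seed Optional integer seed stored with the config.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_proteins = 1000L, n_case = 20L, n_control = 20L,
                          baseline_mean = 10, baseline_sd = 3, noise_sd = 1,
                          n_up = 80L, n_down = 40L, effect_size = 2,
                          dropout_slope = 2, dropout_intercept = -12,
                          exclusive_rate = 0.02, seed = NULL) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_case = as.integer(n_case),
              n_control = as.integer(n_control), baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, noise_sd = noise_sd,
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              effect_size = effect_size, dropout_slope = dropout_slope,
              dropout_intercept = dropout_intercept,
              exclusive_rate = exclusive_rate, seed = seed)
  if (cfg$n_proteins < 1L || cfg$n_case < 1L || cfg$n_control < 1L) {
    abort("Cohort dimensions must be positive.")
  }
  if (cfg$n_up < 0L || cfg$n_down < 0L ||
      cfg$n_up + cfg$n_down > cfg$n_proteins) {
    abort("`n_up + n_down` must not exceed `n_proteins`.")
  }
  if (!is.finite(cfg$effect_size)) abort("`effect_size` must be finite.")
  if (cfg$baseline_sd < 0 || cfg$noise_sd < 0) abort("SDs must be >= 0.")
  if (cfg$exclusive_rate < 0 || cfg$exclusive_rate > 1) {
    abort("`exclusive_rate` must be in [0, 1].")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws an intensity matrix, sample annotation, and a ground-truth record
#' from a [cohort_config()]. Effects are planted on proteins below the
#' top abundance decile: the bulk-mass proteins dominate per-sample
#' totals, and planting strong effects there would turn iFOT
#' renormalization itself into a group signal, which real disease
#' signatures (drawn from the mid/low-abundance proteome) do not do.
#' Passing the `truth` of a previous cohort reuses its planted protein
#' identities, effects, and per-protein baseline abundances, producing an
#' independent validation cohort with the same underlying biology but
#' fresh samples and noise.
#'
#' @param config A [cohort_config()].
#' @param truth Optional `ground_truth` from a previous call to reuse.
#' @return List with `matrix` (intensity tibble), `annotation` (tibble),
#'   and `truth` (a `ground_truth`: `up_proteins`, `down_proteins`,
#'   `effects` and `baseline` named vectors).
#' @export
generate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_if(config$seed, {
    prot <- sprintf("P%04d", seq_len(config$n_proteins))
    samples <- c(sprintf("CASE%02d", seq_len(config$n_case)),
                 sprintf("CTRL%02d", seq_len(config$n_control)))
    is_case <- rep(c(TRUE, FALSE), c(config$n_case, config$n_control))

    if (is.null(truth)) {
      baseline <- stats::setNames(
        rnorm(config$n_proteins, config$baseline_mean, config$baseline_sd), prot)
      # Plant effects in the quantifiable band. Below: proteins whose
      # baseline sits at the detection limit are the group-exclusive
      # class, not the shared-proteome signature the differential test
      # sees. Above: the bulk-mass top decile dominates per-sample
      # totals, and a strong effect there turns iFOT renormalization
      # itself into a group signal.
      det_floor <- (4 - config$dropout_intercept) / config$dropout_slope
      ok <- baseline < stats::quantile(baseline, 0.9)
      if (is.finite(det_floor)) ok <- ok & baseline >= det_floor
      candidates <- prot[ok]
      if (length(candidates) < config$n_up + config$n_down) candidates <- prot
      planted <- sample(candidates, config$n_up + config$n_down)
      up <- planted[seq_len(config$n_up)]
      down <- setdiff(planted, up)
      effects <- stats::setNames(numeric(config$n_proteins), prot)
      effects[up] <- config$effect_size
      effects[down] <- -config$effect_size
    } else {
      stopifnot(inherits(truth, "ground_truth"))
      up <- truth$up_proteins
      down <- truth$down_proteins
      effects <- truth$effects[prot]
      baseline <- truth$baseline[prot]
      if (anyNA(effects) || anyNA(baseline)) {
        abort("`truth` does not cover this protein universe.")
      }
    }
    eff <- matrix(effects[prot], config$n_proteins, length(samples))
    eff[, !is_case] <- 0
    log2abund <- unname(baseline) +
      eff +
      matrix(rnorm(config$n_proteins * length(samples), 0, config$noise_sd),
             config$n_proteins, length(samples))
    intens <- 2^log2abund

    p_detect <- stats::plogis(config$dropout_slope * log2abund +
                                config$dropout_intercept)
    detected <- matrix(runif(length(p_detect)) < p_detect,
                       nrow(p_detect), ncol(p_detect))
    intens[!detected] <- 0

    if (config$exclusive_rate > 0) {
      n_excl <- rbinom(1L, config$n_proteins, config$exclusive_rate)
      if (n_excl > 0L) {
        rows <- sample.int(config$n_proteins, n_excl)
        zero_case <- runif(n_excl) < 0.5
        intens[rows[zero_case], is_case] <- 0
        intens[rows[!zero_case], !is_case] <- 0
      }
    }

    dimnames(intens) <- list(prot, samples)
    out_truth <- structure(
      list(up_proteins = up, down_proteins = down, effects = effects,
           baseline = baseline,
           enriched_tf_names = truth$enriched_tf_names %||% character(),
           config = config),
      class = "ground_truth")
    list(matrix = matrix_to_tbl(intens),
         annotation = tibble(sample = samples,
                             group = ifelse(is_case, "case", "control")),
         truth = out_truth)
  })
}

#' Generate a ChEA-style TF target-set collection with planted enrichment
#'
#' Builds `n_tfs` target sets of `set_size` members drawn from `universe`.
#' Planted TFs draw `round(overlap_fraction * set_size)` members from the
#' ground truth's up-regulated proteins and the remainder uniformly from
#' the rest of the universe; non-planted TFs draw uniformly. The returned
#' truth records the planted TF names.
#'
#' @param universe Character vector of candidate target ids.
#' @param truth `ground_truth` carrying `up_proteins`.
#' @param n_tfs Total number of TF sets.
#' @param set_size Members per set (<= `length(universe)`).
#' @param planted Named numeric vector `c(TF_NAME = overlap_fraction, ...)`
#'   with fractions in \[0, 1\]; its names become set names alongside the
#'   auto-named background TFs.
#' @param seed Optional integer seed.
#' @return List with `collection` (gene-set tibble) and `truth` (updated
#'   with `enriched_tf_names`).
#' @export
generate_tf_collection <- function(universe, truth, n_tfs = 50L, set_size = 30L,
                                   planted = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  universe <- unique(normalize_ids(universe))
  if (set_size > length(universe)) abort("`set_size` exceeds the universe.")
  planted <- planted %||% stats::setNames(numeric(0), character(0))
  if (any(planted < 0 | planted > 1)) abort("Overlap fractions must be in [0, 1].")
  if (length(planted) > n_tfs) abort("More planted TFs than `n_tfs`.")
  up <- intersect(normalize_ids(truth$up_proteins), universe)

  with_seed_if(seed, {
    names_all <- c(names(planted),
                   sprintf("TF%02d", seq_len(n_tfs - length(planted))))
    genes <- vector("list", n_tfs)
    for (i in seq_len(n_tfs)) {
      if (i <= length(planted)) {
        n_in <- round(planted[[i]] * set_size)
        if (n_in > length(up)) {
          abort(sprintf("Planted overlap needs %d up-proteins but only %d exist.",
                        n_in, length(up)))
        }
        core <- sample(up, n_in)
        rest <- sample(setdiff(universe, core), set_size - n_in)
        genes[[i]] <- sample(c(core, rest))
      } else {
        genes[[i]] <- sample(universe, set_size)
      }
    }
    collection <- tibble(set = names_all,
                         description = ifelse(seq_len(n_tfs) <= length(planted),
                                              "planted", "background"),
                         genes = genes)
    truth$enriched_tf_names <- names(planted)
    truth$planted_overlap <- planted
    list(collection = collection, truth = truth)
  })
}
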