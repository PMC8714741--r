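#' Default pipeline configuration
#'
#' Returns the nested list of parameters used across the battery generators,
#' scorers, quality filters and the participant simulator. Values mirror the
#' published design of the assessment battery (20 d2 pages of a 7x6 grid, 40
#' DMTS trials over delays of 0/1/4/12 s with a 4,500 ms prompt, six SWM
#' difficulty levels of 4-14 boxes) and the simulator's calibration constants,
#' which are chosen so that simulated cohorts land near the validation study's
#' metric means and spreads. Any subset can be overridden via
#' [load_config()] or by editing the returned list.
#'
#' @return A named nested list with components `seed`, `palettes`, `d2`,
#'   `dmts`, `swm`, `filters` and `simulate`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$d2$n_pages
default_config <- function() {
  list(
    seed = 1L,
    palettes = list(n_colors = 8L, n_forms = 8L),
    d2 = list(
      n_pages = 20L,
      n_rows = 6L,
      n_cols = 7L,
      # target density follows the classic pen-and-paper d2 (~45% targets);
      # remaining items split evenly over the three distractor classes
      target_prop = 0.45,
      distractor_mix = c(1, 1, 1) / 3,
      page_duration_ms = 15000L
    ),
    dmts = list(
      n_per_delay = 10L,
      delays_ms = c(0L, 1000L, 4000L, 12000L),
      prompt_duration_ms = 4500L,
      order = "interleaved", # or "blocked"
      latency_all_trials = TRUE # average latency over error trials too
    ),
    swm = list(
      box_levels = c(4L, 6L, 8L, 10L, 12L, 14L),
      double_count = TRUE # an open can be both a within and a between error
    ),
    filters = list(
      min_seconds_per_item = 1,
      max_flagged_scales = 2, # "more than two scales" => removed at >= 3
      outlier_sd = 3
    ),
    simulate = list(
      n = 90L,
      age_mean = 37.944,
      age_sd = 11.155,
      age_range = c(18, 72),
      p_male = 57 / 90,
      careless_fraction = 0,
      phq9 = list(
        discrimination = 2.0,
        thresholds = c(0.28, 1.00, 1.72),
        item_spread = 0.35
      ),
      d2 = list(
        items_per_page_mean = 21,
        items_per_page_sd = 3,
        omission_base = -2.55,
        commission_base = -3.0,
        severity_slope = 0.75,
        heterogeneity = 1.1
      ),
      dmts = list(
        fidelity_base = 2.0,
        delay_slope = 0.28, # per sqrt(second of delay)
        severity_slope = 0.55,
        heterogeneity = 0.7,
        error_weights = c(color = 0.23, shape = 0.58, both = 0.19),
        latency_meanlog = 8.15,
        latency_sdlog = 0.45,
        latency_severity_slope = 0.04
      ),
      swm = list(
        error_base = 0.15,
        severity_slope = 0.55,
        heterogeneity = 0.8,
        within_share = 0.16, # fraction of lapses that revisit within-sequence
        start_discipline = 0.05, # prob. of reusing the previous start box
        start_explore = 0.75 # prob. of starting at a box not yet used as a start
      ),
      scales = list(
        aux_ids = c("aux_a", "aux_b", "aux_c"),
        aux_items = c(aux_a = 10L, aux_b = 8L, aux_c = 12L),
        aux_max = 4L,
        seconds_per_item_range = c(1.8, 4)
      )
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()], so a file
#' only needs to name the parameters it changes.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A configuration list as from [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded generation never perturbs
# user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed: mixes a master seed with a short string tag
# so that e.g. the d2 and DMTS batteries of the same participant differ but
# are each exactly reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum((codes %% 64) * (17^(seq_along(codes) %% 7))) %% 2147483647
  as.integer((abs(as.double(seed)) * 48271 + h * 9973 + 1) %% 2147483647)
}
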