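# Region order used by the demographic model and the compiled core.
# Deme indices: Africa, Oceania, Europe, Central Asia, East Asia, America.
DEME_ORDER <- c("Africa", "Oceania", "Europe", "Central Asia",
                "East Asia", "America")

#' Serial-founder demographic model
#'
#' The model begins with an ancestral population in Africa at time `T1`
#' (onset of African growth), a single out-of-Africa migration at `T2`, the
#' split of Oceania from the remaining non-Africans at `T3`, Europe from
#' Asia at `T4`, Central from East Asia at `T5`, and East Asia from America
#' at `T6`. There is no migration after divergence. Within each terminal
#' regional branch the effective size grows exponentially from its founding
#' size to its current size; ancestral non-African (backbone) branches are
#' constant at the out-of-Africa founder size `n_ooa`; before `T1` the
#' African population is constant at `n_anc_africa`. All sizes are haploid
#' effective sizes of the transmitting sex (female for mtDNA, male for the
#' NRY).
#'
#' @param times Named numeric of event times in years, names `T1`..`T6`,
#'   with `T1 > T2 > T3 > T4 > T5 > T6 > 0`.
#' @param n_anc_africa Ancestral (and founding) African size.
#' @param n_ooa Out-of-Africa founder size.
#' @param n_anc Named numeric: founding sizes for Oceania, Europe,
#'   Central Asia, East Asia, America.
#' @param n_cur Named numeric: current sizes for all six regions.
#' @param generation_time Years per generation (default 25). Rates are
#'   specified per year, so inferred sizes scale as `1 / generation_time`.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(times, n_anc_africa, n_ooa, n_anc, n_cur,
                              generation_time = 25) {
  times <- times[paste0("T", 1:6)]
  if (anyNA(times)) abort("`times` must be named T1..T6.")
  if (any(diff(unname(times)) >= 0) || times[["T6"]] <= 0) {
    abort("Model error: need T1 > T2 > T3 > T4 > T5 > T6 > 0.")
  }
  need_anc <- c("Oceania", "Europe", "Central Asia", "East Asia", "America")
  if (anyNA(n_anc[need_anc])) abort("`n_anc` must name the 5 non-African regions.")
  if (anyNA(n_cur[DEME_ORDER])) abort("`n_cur` must name all 6 regions.")
  sizes <- c(n_anc_africa, n_ooa, unname(n_anc[need_anc]),
             unname(n_cur[DEME_ORDER]))
  if (any(sizes < 1)) abort("All effective sizes must be >= 1.")
  structure(
    list(times = times, n_anc_africa = n_anc_africa, n_ooa = n_ooa,
         n_anc = n_anc[need_anc], n_cur = n_cur[DEME_ORDER],
         generation_time = generation_time),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> serial-founder, 6 regions\n")
  cat("  times (ky):", paste(sprintf("%s=%.1f", names(x$times),
                                     x$times / 1000), collapse = " "), "\n")
  cat("  N_anc_africa =", x$n_anc_africa, " N_ooa =", x$n_ooa,
      " g =", x$generation_time, "yr\n")
  invisible(x)
}

#' @method tidy demographic_model
#' @export
tidy.demographic_model <- function(x, ...) {
  tibble::tibble(
    parameter = c(names(x$times), "N_anc_Africa", "N_ooa",
                  paste0("N_anc_", gsub(" ", "", names(x$n_anc))),
                  paste0("N_cur_", gsub(" ", "", names(x$n_cur)))),
    value = c(unname(x$times), x$n_anc_africa, x$n_ooa,
              unname(x$n_anc), unname(x$n_cur))
  )
}

# Flatten a model into the 19-element vector (times in generations,
# then the 13 sizes) consumed by the compiled simulator.
model_to_param_row <- function(model) {
  g <- model$generation_time
  c(unname(model$times) / g, model$n_anc_africa, model$n_ooa,
    unname(model$n_anc), unname(model$n_cur))
}

# Size-parameter names in compiled-core order (13).
SIZE_PARAMS <- c("N_anc_Africa", "N_ooa", "N_anc_Oceania", "N_anc_Europe",
                 "N_anc_CentralAsia", "N_anc_EastAsia", "N_anc_America",
                 "N_cur_Africa", "N_cur_Oceania", "N_cur_Europe",
                 "N_cur_CentralAsia", "N_cur_EastAsia", "N_cur_America")
TIME_PARAMS <- paste0("T", 1:6)

#' Default demographic model of the study conditions
#'
#' Point estimates used as the "true" model by the synthetic-data
#' generator: divergence times are the posterior means of the combined-locus
#' analysis, sizes the posterior means of the per-locus size analyses.
#'
#' @param locus `"NRY"` (male sizes) or `"mtDNA"` (female sizes).
#' @param generation_time Years per generation.
#' @return A [demographic_model()].
#' @export
default_model <- function(locus = c("NRY", "mtDNA"), generation_time = 25) {
  locus <- match.arg(locus)
  times <- c(T1 = 107067, T2 = 74916, T3 = 63210, T4 = 49280,
             T5 = 36700, T6 = 15828)
  if (locus == "NRY") {
    demographic_model(
      times, n_anc_africa = 32, n_ooa = 15,
      n_anc = c(Oceania = 30, Europe = 18, `Central Asia` = 74,
                `East Asia` = 4935, America = 21),
      n_cur = c(Africa = 6565, Oceania = 2060, Europe = 3815,
                `Central Asia` = 8579, `East Asia` = 22009, America = 685),
      generation_time = generation_time
    )
  } else {
    demographic_model(
      times, n_anc_africa = 57, n_ooa = 26,
      n_anc = c(Oceania = 52, Europe = 118, `Central Asia` = 1663,
                `East Asia` = 4710, America = 90),
      n_cur = c(Africa = 11505, Oceania = 3509, Europe = 8029,
                `Central Asia` = 29513, `East Asia` = 100111,
                America = 1802),
      generation_time = generation_time
    )
  }
}

#' Locus specification
#'
#' Mutational model of a haploid non-recombining locus: one or more
#' partitions with a length (bp) and a substitution rate per site per year.
#' Defaults: mtDNA = non-coding (1,122 bp at 9.883e-8) + coding (15,447 bp
#' at 1.708e-8); NRY = a single 501,108 bp partition at the fast
#' (1.00e-9), slow (6.17e-10) or averaged (8.085e-10) rate.
#'
#' @param type `"mtDNA"` or `"NRY"`.
#' @param nry_rate `"avg"`, `"fast"`, `"slow"`, or a numeric rate.
#' @return A tibble (class `locus_spec`) with columns `partition`, `length`,
#'   `rate` and a `locus` attribute.
#' @export
locus_spec <- function(type = c("mtDNA", "NRY"),
                       nry_rate = c("avg", "fast", "slow")) {
  type <- match.arg(type)
  if (type == "mtDNA") {
    out <- tibble::tibble(
      partition = c("non-coding", "coding"),
      length = c(1122, 15447),
      rate = c(9.883e-8, 1.708e-8)
    )
  } else {
    rate <- if (is.numeric(nry_rate)) nry_rate else
      switch(match.arg(nry_rate), fast = 1.00e-9, slow = 6.17e-10,
             avg = (1.00e-9 + 6.17e-10) / 2)
    out <- tibble::tibble(partition = "NRY", length = 501108, rate = rate)
  }
  if (any(out$length <= 0) || any(out$rate <= 0)) {
    abort("Partition lengths and rates must be positive.")
  }
  attr(out, "locus") <- type
  class(out) <- c("locus_spec", class(out))
  out
}

# Expected mutations per generation of branch length for a locus.
locus_mu_gen <- function(locus, generation_time) {
  sum(locus$length * locus$rate) * generation_time
}

#' Regional sample configuration
#'
#' @param counts Named integer vector of haploid sample counts per region;
#'   defaults to the 511 male samples of the study design (Africa 85,
#'   Central Asia 146, East Asia 162, Europe 79, Oceania 17, America 22).
#' @return Named integer vector in model deme order.
#' @export
sample_config <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- c(Africa = 85L, Oceania = 17L, Europe = 79L,
                `Central Asia` = 146L, `East Asia` = 162L, America = 22L)
  }
  out <- setNames(integer(length(DEME_ORDER)), DEME_ORDER)
  out[names(counts)] <- as.integer(counts)
  if (any(out < 0)) abort("Sample counts must be >= 0.")
  if (sum(out) < 1) abort("Need at least one sample.")
  out
}

#' Uniform / log-uniform priors for the demographic parameters
#'
#' Divergence-time priors are uniform in years (`T1` 100-150k, `T2` 60-100k,
#' `T3` 60-100k, `T4` 40-60k, `T5` 20-40k, `T6` 10-20k); draws violating the
#' strict ordering (in particular `T2 > T3`) are rejected and redrawn.
#' Size priors are log-uniform: founding sizes on \[1, 1e4\], current sizes
#' on \[1e2, 2e5\].
#'
#' @param time_ranges,size_ranges Optional named lists of `c(lo, hi)`
#'   ranges overriding the defaults.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(time_ranges = NULL, size_ranges = NULL) {
  tr <- list(T1 = c(100000, 150000), T2 = c(60000, 100000),
             T3 = c(60000, 100000), T4 = c(40000, 60000),
             T5 = c(20000, 40000), T6 = c(10000, 20000))
  sr <- c(
    setNames(rep(list(c(1, 1e4)), 7),
             SIZE_PARAMS[1:7]),
    setNames(rep(list(c(1e2, 2e5)), 6), SIZE_PARAMS[8:13])
  )
  if (!is.null(time_ranges)) tr[names(time_ranges)] <- time_ranges
  if (!is.null(size_ranges)) sr[names(size_ranges)] <- size_ranges
  for (r in c(tr, sr)) {
    if (length(r) != 2 || r[2] < r[1] || r[1] <= 0) {
      abort("Each prior range must be c(lo, hi) with 0 < lo <= hi.")
    }
  }
  structure(list(time = tr, size = sr), class = "prior_spec")
}

#' Draw demographic parameters from the priors
#'
#' Times are uniform, sizes log-uniform; joint draws violating the time
#' ordering `T1 > T2 > T3 > T4 > T5 > T6` are rejected and redrawn, which
#' in particular enforces `T2 > T3` whose priors overlap.
#'
#' @param priors A [prior_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A tibble of `n` rows with columns `T1..T6` and the 13 size
#'   parameters, in years / haploid individuals.
#' @export
draw_parameters <- function(priors, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_times <- function(k) {
    tm <- vapply(priors$time, function(r) runif(k, r[1], r[2]),
                 numeric(k))
    if (k == 1) tm <- matrix(tm, nrow = 1, dimnames = list(NULL, TIME_PARAMS))
    tm
  }
  tm <- draw_times(n)
  bad <- which(apply(tm, 1, function(x) any(diff(x) >= 0)))
  while (length(bad)) {
    tm[bad, ] <- draw_times(length(bad))
    bad <- bad[apply(tm[bad, , drop = FALSE], 1,
                     function(x) any(diff(x) >= 0))]
  }
  sz <- vapply(priors$size, function(r) {
    exp(runif(n, log(r[1]), log(r[2])))
  }, numeric(n))
  if (n == 1) sz <- matrix(sz, nrow = 1, dimnames = list(NULL, SIZE_PARAMS))
  out <- tibble::as_tibble(cbind(tm, sz))
  names(out) <- c(TIME_PARAMS, SIZE_PARAMS)
  out
}

# Convert a parameter tibble (years) to the compiled-core matrix
# (generations).
params_to_matrix <- function(params, generation_time) {
  m <- as.matrix(params[c(TIME_PARAMS, SIZE_PARAMS)])
  m[, TIME_PARAMS] <- m[, TIME_PARAMS] / generation_time
  m
}
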