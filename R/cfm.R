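#' CFM-CC growth parameters for one species
#'
#' The coarse-grained cell-flux growth model reduces a species to a
#' maximum photosynthesis rate `pmax` and a constant respiration rate `m`
#' (both d^-1); growth is photosynthesis scaled by the environmental
#' nutrient repletion factor minus respiration.
#'
#' @param species Species label.
#' @param pmax Maximum photosynthesis rate (d^-1, > 0).
#' @param m Respiration rate (d^-1, >= 0).
#' @return A `cfm_params` object.
#' @export
cfm_params <- function(species, pmax, m) {
  assert_num(pmax, "pmax", lower = 0, strict_lower = TRUE)
  assert_num(m, "m", lower = 0)
  structure(list(species = as.character(species), pmax = pmax, m = m),
            class = "cfm_params")
}

#' CFM-CC growth rate
#'
#' \deqn{\mu = P_{max} f_N - m}
#' where `fN` in \[0, 1\] expresses environmental nutrient repletion
#' (0 = fully deplete, 1 = replete). Growth may be negative when
#' respiration exceeds nutrient-limited photosynthesis.
#'
#' @param p A [cfm_params()].
#' @param fN Nutrient repletion factor(s) in \[0, 1\]. Vectorized.
#' @return Growth rate(s), d^-1.
#' @export
growth_rate <- function(p, fN) {
  stopifnot(inherits(p, "cfm_params"))
  if (!is.numeric(fN) || anyNA(fN) || any(fN < 0) || any(fN > 1)) {
    dzd_stop("domain_error", "fN must lie in [0, 1]")
  }
  p$pmax * fN - p$m
}

#' Nutrient repletion factor at which two growth laws cross
#'
#' Because both growth laws are linear in `fN`, they intersect at
#' `fN* = (m_b - m_a) / (pmax_b - pmax_a)` when the slopes differ; the
#' crossover is reported only when it falls inside \[0, 1\].
#'
#' @param a,b [cfm_params()] for the two species.
#' @return A list with `status` (`"crossover"`, `"absent"` or
#'   `"identical"`) and `fN` (the crossover value, or `NA`).
#' @export
crossover_fN <- function(a, b) {
  stopifnot(inherits(a, "cfm_params"), inherits(b, "cfm_params"))
  if (a$pmax == b$pmax) {
    if (a$m == b$m) {
      return(list(status = "identical", fN = NA_real_))
    }
    return(list(status = "absent", fN = NA_real_))
  }
  fn <- (b$m - a$m) / (b$pmax - a$pmax)
  if (fn >= 0 && fn <= 1) {
    list(status = "crossover", fN = fn)
  } else {
    list(status = "absent", fN = NA_real_)
  }
}

#' Two-species competition over the nutrient repletion gradient
#'
#' Evaluates both growth laws on a uniform `fN` grid over \[0, 1\] and
#' labels the winner (strictly larger growth rate) at each point; exact
#' equality is labelled `"tie"`. Linearity guarantees the winner sequence
#' has at most one transition.
#'
#' @param a,b [cfm_params()] for the two species.
#' @param n_grid Number of grid points (>= 2).
#' @return A `competition_result`: data frame `fN, mu_a, mu_b, winner`
#'   plus the analytic [crossover_fN()] in attribute `crossover`.
#' @export
run_competition <- function(a, b, n_grid = 101L) {
  stopifnot(inherits(a, "cfm_params"), inherits(b, "cfm_params"))
  if (!is.numeric(n_grid) || n_grid < 2L) {
    dzd_stop("config_error", "n_grid must be >= 2")
  }
  fN <- seq(0, 1, length.out = as.integer(n_grid))
  mu_a <- growth_rate(a, fN)
  mu_b <- growth_rate(b, fN)
  winner <- ifelse(mu_a > mu_b, a$species,
                   ifelse(mu_b > mu_a, b$species, "tie"))
  out <- data.frame(fN = fN, mu_a = mu_a, mu_b = mu_b, winner = winner)
  structure(out, crossover = crossover_fN(a, b),
            species = c(a = a$species, b = b$species),
            class = c("competition_result", "data.frame"))
}

#' Map measured phase budgets onto CFM-CC parameters
#'
#' Converts a species' measured day-phase gross O2 evolution into `pmax`
#' and its total daily respiration (day + night) into `m` through a single
#' proportionality constant. The constant cancels from the crossover
#' location's sign structure; the parameterization preserves the measured
#' ordering of photosynthetic and respiratory capacity between species,
#' which alone determines who wins at which end of the nutrient gradient.
#'
#' @param phys A `species_physiology` record.
#' @param k_scale d^-1 per (umol O2 (ug Chl)^-1 12 h^-1); default 1.
#' @return A [cfm_params()].
#' @export
cfm_from_physiology <- function(phys, k_scale = 1) {
  stopifnot(inherits(phys, "species_physiology"))
  assert_num(k_scale, "k_scale", lower = 0, strict_lower = TRUE)
  cfm_params(phys$species,
             pmax = k_scale * phys$o2_evolution[["day"]],
             m = k_scale * sum(phys$respiration))
}

#' Write a competition grid as CSV (`fN,mu_a,mu_b,winner`)
#' @param res A `competition_result`.
#' @param path Output path.
#' @export
write_competition <- function(res, path) {
  write_dzd_csv(as.data.frame(res), path)
}

#' Write the analytic crossover as JSON
#' @param res A `competition_result` (or a [crossover_fN()] list).
#' @param path Output path.
#' @export
write_crossover <- function(res, path) {
  x <- if (inherits(res, "competition_result")) attr(res, "crossover") else res
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
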