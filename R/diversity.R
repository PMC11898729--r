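#' Abundance vector of locus types
#'
#' Each sampling unit (a SAG or a long read) carries exactly one typed
#' island, so incidence- and abundance-based richness machinery coincide and
#' the abundance (Chao1) form is used throughout.
#'
#' @param x Positive integer counts per type (optionally named), or pass
#'   `assignment` + `units` instead.
#' @param assignment An `obc_type_assignment` (alternative constructor).
#' @param units Character vector of unit ids (island ids) to count; every
#'   unit must be typed.
#' @return An `obc_abundance`: list with `x`, `n`, `S_obs`, `f1`, `f2`.
#' @export
abundance_vector <- function(x = NULL, assignment = NULL, units = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(assignment), !is.null(units))
    a <- assignment$assignment
    idx <- match(units, a$island_id)
    if (anyNA(idx)) {
      abort("some units have no type assignment", class = "obc_div_error")
    }
    x <- table(a$type_id[idx])
    x <- setNames(as.integer(x), names(x))
  }
  x <- x[x > 0]
  if (!length(x) || any(x != round(x))) {
    abort("counts must be positive integers", class = "obc_div_error")
  }
  structure(list(x = as.integer(x), n = as.integer(sum(x)),
                 S_obs = length(x),
                 f1 = sum(x == 1L), f2 = sum(x == 2L)),
            class = "obc_abundance")
}

#' @export
print.obc_abundance <- function(x, ...) {
  cat("<obc_abundance> n=", x$n, " S_obs=", x$S_obs, " f1=", x$f1,
      " f2=", x$f2, "\n", sep = "")
  invisible(x)
}

#' Analytic rarefaction: expected richness at subsample size m
#'
#' `S(m) = S_obs - sum_i C(n - x_i, m) / C(n, m)`, evaluated in log space for
#' stability at large n. `S(n) = S_obs` exactly and `S(1) = 1`.
#'
#' @param v An [abundance_vector()].
#' @param m Subsample sizes, `1 <= m <= n` (vectorised).
#' @return Expected richness values.
#' @export
rarefy <- function(v, m) {
  stopifnot(inherits(v, "obc_abundance"))
  if (any(m < 1 | m > v$n)) {
    abort("m must satisfy 1 <= m <= n (use extrapolate beyond n)",
          class = "obc_div_error")
  }
  vapply(m, function(mm) {
    lc <- lchoose(v$n - v$x, mm) - lchoose(v$n, mm)
    v$S_obs - sum(exp(lc[v$n - v$x >= mm]))
  }, numeric(1))
}

#' Chao1 asymptotic richness
#'
#' `S_obs + f1^2 / (2 f2)` with doubletons, otherwise the bias-corrected form
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`.
#'
#' @param v An [abundance_vector()].
#' @return Estimated total richness.
#' @export
chao_asymptote <- function(v) {
  stopifnot(inherits(v, "obc_abundance"))
  if (v$f2 > 0) v$S_obs + v$f1^2 / (2 * v$f2)
  else v$S_obs + v$f1 * (v$f1 - 1) / (2 * (v$f2 + 1))
}

#' Extrapolated richness at sample size n + m_star
#'
#' `S(n + m*) = S_obs + f0 [1 - (1 - f1 / (n f0 + f1))^{m*}]` with
#' `f0 = chao_asymptote - S_obs`; continuous with [rarefy()] at `m* = 0`,
#' monotone, and bounded by the asymptote. With no singletons the curve is
#' flat at `S_obs`.
#'
#' @param v An [abundance_vector()].
#' @param m_star Additional units beyond n, `>= 0` (vectorised).
#' @return Expected richness values.
#' @export
extrapolate <- function(v, m_star) {
  stopifnot(inherits(v, "obc_abundance"), all(m_star >= 0))
  f0 <- chao_asymptote(v) - v$S_obs
  if (v$f1 == 0 || f0 <= 0) return(rep(as.numeric(v$S_obs), length(m_star)))
  v$S_obs + f0 * (1 - (1 - v$f1 / (v$n * f0 + v$f1))^m_star)
}

#' Detected over predicted richness
#'
#' @param v An [abundance_vector()].
#' @param method `"chao"` (S_obs / Chao1 asymptote) or `"good_turing"`
#'   (sample coverage `1 - f1/n`).
#' @return A ratio in (0, 1].
#' @export
coverage_ratio <- function(v, method = c("chao", "good_turing")) {
  method <- match.arg(method)
  if (method == "chao") v$S_obs / chao_asymptote(v)
  else 1 - v$f1 / v$n
}

#' Chao-style bootstrap confidence intervals for the richness curve
#'
#' Builds a bootstrap community from the data: observed types keep their
#' sample proportions scaled to the estimated sample coverage, and
#' `round(f0)` unseen types share the estimated missing probability equally.
#' `B` multinomial resamples of n units are drawn, the rarefaction /
#' extrapolation curve recomputed on each, and normal-approximation intervals
#' (`+/- z * SD`) are placed around the point estimates. Deterministic given
#' `seed`.
#'
#' @param v An [abundance_vector()].
#' @param levels Sample sizes (values <= n use [rarefy()], larger ones
#'   [extrapolate()]).
#' @param B Bootstrap replicates (>= 50).
#' @param seed Integer seed.
#' @param ci_level Confidence level (default 0.95).
#' @return Tibble: `m`, `S`, `lo`, `hi`, `branch`.
#' @export
bootstrap_ci <- function(v, levels, B = 200L, seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(v, "obc_abundance"), B >= 50L)
  point <- curve_at(v, levels)
  z <- qnorm(1 - (1 - ci_level) / 2)
  f0 <- max(0, round(chao_asymptote(v) - v$S_obs))
  cover <- if (v$n > 0) 1 - v$f1 / v$n else 1
  probs <- c(v$x / v$n * cover, rep((1 - cover) / f0, f0))
  if (sum(probs) <= 0) probs <- v$x / v$n
  sims <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      cnt <- as.integer(stats::rmultinom(1, v$n, probs))
      vb <- abundance_vector(cnt[cnt > 0])
      curve_at(vb, levels)
    }, numeric(length(levels)))
  })
  sims <- matrix(sims, nrow = length(levels))
  sdv <- apply(sims, 1, sd)
  tibble(m = levels, S = point,
         lo = pmax(0, point - z * sdv), hi = point + z * sdv,
         branch = ifelse(levels <= v$n, "rarefaction", "extrapolation"))
}

curve_at <- function(v, levels) {
  out <- numeric(length(levels))
  lo <- levels <= v$n
  if (any(lo)) out[lo] <- rarefy(v, levels[lo])
  if (any(!lo)) out[!lo] <- extrapolate(v, levels[!lo] - v$n)
  out
}

#' Full rarefaction and extrapolation curve with confidence band
#'
#' @param v An [abundance_vector()].
#' @param extrapolate_to Largest sample size (default `2 * n`).
#' @param n_points Number of curve points.
#' @param B,seed,ci_level Passed to [bootstrap_ci()].
#' @return List: `curve` (tibble m, S, lo, hi, branch), `asymptote`,
#'   `coverage` (detected/predicted), `summary`.
#' @export
rarefaction_curve <- function(v, extrapolate_to = 2L * v$n, n_points = 40L,
                              B = 200L, seed = 1L, ci_level = 0.95) {
  levels <- unique(sort(c(1L, v$n,
                          as.integer(round(seq(1, extrapolate_to,
                                               length.out = n_points))))))
  curve <- bootstrap_ci(v, levels, B = B, seed = seed, ci_level = ci_level)
  list(curve = curve,
       asymptote = chao_asymptote(v),
       coverage = coverage_ratio(v),
       summary = tibble(n = v$n, S_obs = v$S_obs, f1 = v$f1, f2 = v$f2,
                        asymptote = chao_asymptote(v),
                        coverage = coverage_ratio(v)))
}
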