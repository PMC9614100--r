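# Dempster-Shafer evidence on the two-element frame {target, non-target}.
# The power set adds the empty set (always mass 0) and the composite
# {target, non-target}, which carries the "uncertain" mass.

#' Construct a mass function on the target / non-target frame
#'
#' @param target,nontarget,uncertain basic probability masses in \[0, 1\]
#'   assigned to \{target\}, \{non-target\} and the composite
#'   \{target, non-target\}; must sum to 1 (tolerance 1e-12); the empty set
#'   always receives 0.
#' @return an object of class `mass_function` (named numeric triple).
#' @export
mass_function <- function(target, nontarget, uncertain) {
  m <- c(target = target, nontarget = nontarget, uncertain = uncertain)
  if (any(!is.finite(m)) || any(m < -1e-12) || any(m > 1 + 1e-12))
    stop_dpifuse("masses must lie in [0, 1]", "dpifuse_validation_error")
  if (abs(sum(m) - 1) > 1e-9)
    stop_dpifuse(sprintf("masses must sum to 1 (got %.12f)", sum(m)),
                 "dpifuse_validation_error")
  m <- pmin(1, pmax(0, m))
  names(m) <- c("target", "nontarget", "uncertain")
  structure(m, class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat(sprintf("<mass_function> m(target)=%.4f m(non-target)=%.4f m(uncertain)=%.4f\n",
              x[["target"]], x[["nontarget"]], x[["uncertain"]]))
  invisible(x)
}

# Vectorised Dempster combination on n x 3 mass matrices
# (columns target, nontarget, uncertain). Returns list(mass, conflict).
dempster_rows <- function(M1, M2) {
  K <- M1[, 1L] * M2[, 2L] + M1[, 2L] * M2[, 1L]
  mt <- M1[, 1L] * M2[, 1L] + M1[, 1L] * M2[, 3L] + M1[, 3L] * M2[, 1L]
  mn <- M1[, 2L] * M2[, 2L] + M1[, 2L] * M2[, 3L] + M1[, 3L] * M2[, 2L]
  mu <- M1[, 3L] * M2[, 3L]
  denom <- 1 - K
  ok <- denom >= 1e-12
  out <- cbind(target = ifelse(ok, mt / denom, NA_real_),
               nontarget = ifelse(ok, mn / denom, NA_real_),
               uncertain = ifelse(ok, mu / denom, NA_real_))
  list(mass = out, conflict = K, total_conflict = !ok,
       unnormalized = cbind(mt, mn, mu))
}

#' Combine two mass functions with Dempster's rule
#'
#' Normalised intersection combination: the conflict mass
#' `K = m1(t) m2(nt) + m1(nt) m2(t)` is discounted by renormalising with
#' `1 - K`. Commutative and associative; the vacuous mass (0, 0, 1) is the
#' identity. Total conflict (`1 - K < 1e-12`) raises an explicit error
#' carrying `K` rather than returning NaN.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return the combined [mass_function()].
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  res <- dempster_rows(matrix(unclass(m1), 1L), matrix(unclass(m2), 1L))
  if (res$total_conflict[1L])
    stop_dpifuse(sprintf("total conflict between the two masses (K = %.12f)",
                         res$conflict[1L]),
                 "dpifuse_total_conflict_error", conflict = res$conflict[1L])
  mass_function(res$mass[1L, 1L], res$mass[1L, 2L], res$mass[1L, 3L])
}

#' Pignistic decision transform
#'
#' In the form used for the decision rule, the uncertain mass is added in
#' full to both singletons: `P_pig(target) = m(target) + m(uncertain)` and
#' `P_pig(non-target) = m(non-target) + m(uncertain)` — so the two values
#' sum to `1 + m(uncertain)`. The classical variant that splits the
#' composite mass evenly between the two singletons is available with
#' `split_uncertain = TRUE`.
#'
#' @param m a [mass_function()].
#' @param split_uncertain halve the uncertain mass between the singletons
#'   instead of double-counting it (default `FALSE`).
#' @return named numeric `c(target = , nontarget = )`.
#' @export
pignistic <- function(m, split_uncertain = FALSE) {
  stopifnot(inherits(m, "mass_function"))
  share <- if (split_uncertain) m[["uncertain"]] / 2 else m[["uncertain"]]
  c(target = m[["target"]] + share, nontarget = m[["nontarget"]] + share)
}
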