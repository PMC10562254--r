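#' Partition markers into a candidate region and the rest of the genome
#'
#' The candidate region is the window of total width `radius_bp` centered
#' on an association peak (default 1 Mb), so markers within +/- radius/2 of
#' the peak are in-region; the partition is disjoint and exhaustive.
#'
#' @param map marker map data.frame (`chrom`, `pos`).
#' @param chrom,pos peak chromosome and position.
#' @param radius_bp total window width (default 1e6).
#' @return list with integer index vectors `in_region` and `out_region`.
#' @export
split_region <- function(map, chrom, pos, radius_bp = 1e6) {
  inr <- which(map$chrom == chrom & abs(map$pos - pos) <= radius_bp / 2)
  if (length(inr) == 0L) stop("no markers in the candidate region")
  outr <- setdiff(seq_len(nrow(map)), inr)
  if (length(outr) == 0L) stop("no markers outside the candidate region")
  list(in_region = inr, out_region = outr)
}

#' Fit the four-random-effect regional variance model
#'
#' y = L b + u_a1 + u_d1 + u_a2 + u_d2 + e, with additive and dominance
#' kernels built separately from the in-region and out-region markers and
#' all five variance components estimated by REML (non-negativity enforced
#' at the boundary).
#'
#' @param y phenotype vector.
#' @param X fixed-effect design (default intercept only).
#' @param A_in,D_in,A_out,D_out relationship matrices from
#'   [build_relationship_matrices()] on the two marker sets.
#' @param ... passed to [fit_reml()].
#' @return list of class `region_variance_model`: `sigma2` named
#'   (`ua1`, `ud1`, `ua2`, `ud2`, `e`), `converged`, `loglik`, `fit`.
#' @export
fit_region_model <- function(y, X = NULL, A_in, D_in, A_out, D_out, ...) {
  fit <- fit_reml(y, X, K = list(A_in, D_in, A_out, D_out), ...)
  s2 <- fit$sigma2
  names(s2) <- c("ua1", "ud1", "ua2", "ud2", "e")
  if (!fit$converged)
    warning("regional REML did not converge within the iteration cap")
  structure(list(sigma2 = s2, converged = fit$converged,
                 loglik = fit$loglik, fit = fit),
            class = "region_variance_model")
}

#' Genetic proportion and PVE of the candidate region
#'
#' Genetic proportion = (s2_ua1 + s2_ud1) / (s2_ua1 + s2_ud1 + s2_ua2 +
#' s2_ud2); PVE adds the residual variance to the denominator. Undefined
#' (NA, flagged) when all four genetic components are zero.
#'
#' @param model `region_variance_model` or a named numeric vector
#'   (`ua1`, `ud1`, `ua2`, `ud2`, `e`).
#' @return list: `genetic_proportion`, `pve`, `defined`.
#' @export
compute_pve <- function(model) {
  s2 <- if (inherits(model, "region_variance_model")) model$sigma2 else model
  stopifnot(all(c("ua1", "ud1", "ua2", "ud2", "e") %in% names(s2)))
  reg <- s2[["ua1"]] + s2[["ud1"]]
  gen <- reg + s2[["ua2"]] + s2[["ud2"]]
  if (gen <= 0)
    return(list(genetic_proportion = NA_real_, pve = NA_real_, defined = FALSE))
  list(genetic_proportion = reg / gen, pve = reg / (gen + s2[["e"]]),
       defined = TRUE)
}
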