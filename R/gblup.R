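#' Additive and dominance genomic relationship matrices
#'
#' A = W W' / (2 sum_j p_j (1 - p_j)) with W the column-centered -1/0/1
#' additive coding, and D = H H' / denom with H the column-centered 0/1
#' heterozygosity coding. The default dominance denominator is the same
#' 2 sum p(1-p) as for A; the canonical alternative sum (2 p q)^2 is
#' available via `d_denominator = "canonical"`. Allele frequencies are
#' computed from the input cohort; monomorphic markers are dropped with a
#' warning and missing genotypes are mean-imputed per marker.
#'
#' @param gm geno_matrix (or plain dosage matrix).
#' @param d_denominator `"shared"` (default) or `"canonical"`.
#' @return list of class `relationship_matrices`: `A`, `D`, `p` (alt-allele
#'   frequencies of the markers used), `m` (marker count).
#' @export
build_relationship_matrices <- function(gm, d_denominator = c("shared", "canonical")) {
  d_denominator <- match.arg(d_denominator)
  g <- if (inherits(gm, "geno_matrix")) gm$geno else as.matrix(gm)
  storage.mode(g) <- "double"
  cm <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- cm[j]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic")
  if (any(!poly))
    warning(sum(!poly), " monomorphic marker(s) dropped")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(g - 1, 2, colMeans(g - 1))
  het <- (g == 1) * 1
  H <- sweep(het, 2, colMeans(het))
  denomA <- 2 * sum(p * (1 - p))
  denomD <- if (d_denominator == "shared") denomA else sum((2 * p * (1 - p))^2)
  structure(list(A = tcrossprod(W) / denomA, D = tcrossprod(H) / denomD,
                 p = p, m = length(p)),
            class = "relationship_matrices")
}

#' Fit a GBLUP model (additive, optionally plus dominance)
#'
#' y = X beta + u_a + u_d + eps with u_a ~ N(0, A s2_a) and, when D is
#' supplied, u_d ~ N(0, D s2_d). Variance components by REML; the GEBV is
#' the additive BLUP, with the dominance BLUP reported separately and the
#' total genetic value being their sum.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design (default intercept).
#' @param A additive relationship matrix.
#' @param D dominance relationship matrix or NULL for additive-only.
#' @param ... passed to [fit_reml()].
#' @return list of class `gblup_fit`: `sigma2` (named), `beta`, `gebv`
#'   (additive BLUP), `dominance_values` (or NULL), `total_genetic`,
#'   `h2` (narrow-sense estimate s2_a / total), `converged`, `loglik`.
#' @export
fit_gblup <- function(y, X = NULL, A, D = NULL, ...) {
  K <- if (is.null(D)) list(A) else list(A, D)
  fit <- fit_reml(y, X, K, ...)
  s2 <- fit$sigma2
  names(s2) <- if (is.null(D)) c("a", "e") else c("a", "d", "e")
  gebv <- fit$blup[[1]]
  dv <- if (is.null(D)) NULL else fit$blup[[2]]
  structure(list(sigma2 = s2, beta = fit$beta, gebv = gebv,
                 dominance_values = dv,
                 total_genetic = gebv + if (is.null(dv)) 0 else dv,
                 h2 = s2[["a"]] / sum(s2),
                 converged = fit$converged, loglik = fit$loglik),
            class = "gblup_fit")
}

#' Cross-validated prediction accuracy of a GBLUP model
#'
#' k-fold cross-validation repeated `iterations` times: within each fold the
#' model is refit on the training individuals and held-out GEBVs are
#' predicted from the training-candidate relationship block. Accuracy is
#' the Pearson correlation between predicted GEBV and observed phenotype on
#' the held-out folds, averaged over folds and iterations. Folds with a
#' constant held-out phenotype are skipped with a message.
#'
#' @param y phenotype vector.
#' @param A additive relationship matrix (full cohort).
#' @param D optional dominance matrix.
#' @param k folds (default 6).
#' @param iterations repeats with fresh fold assignments (default 3).
#' @param seed fold-assignment seed.
#' @return list: `accuracy` (mean), `per_fold` data.frame (iteration, fold,
#'   r, n_test).
#' @export
cross_validate <- function(y, A, D = NULL, k = 6L, iterations = 3L, seed = 1L) {
  n <- length(y)
  stopifnot(n >= 2 * k)
  set.seed(seed)
  rows <- list()
  for (it in seq_len(iterations)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (stats::var(y[test]) == 0) {
        message("fold ", f, " iteration ", it, " skipped: constant phenotype")
        next
      }
      fit <- fit_gblup(y[train], NULL,
                       A[train, train, drop = FALSE],
                       if (is.null(D)) NULL else D[train, train, drop = FALSE])
      pred <- predict_from_blocks(A[test, train, drop = FALSE],
                                  A[train, train, drop = FALSE], fit$gebv)
      if (!is.null(D))
        pred <- pred + predict_from_blocks(D[test, train, drop = FALSE],
                                           D[train, train, drop = FALSE],
                                           fit$dominance_values)
      rows[[length(rows) + 1L]] <-
        data.frame(iteration = it, fold = f,
                   r = stats::cor(pred, y[test]), n_test = length(test))
    }
  }
  per_fold <- do.call(rbind, rows)
  list(accuracy = mean(per_fold$r), per_fold = per_fold)
}

# candidate-training relationship blocks in the training cohort's coding:
# allele frequencies, centering and denominators all come from the training
# individuals, so a candidate equal to a training line reproduces its row
joint_blocks <- function(gt, gc, d_denominator = "shared") {
  storage.mode(gt) <- "double"; storage.mode(gc) <- "double"
  cm <- colMeans(gt, na.rm = TRUE)
  for (j in which(colSums(is.na(gt)) > 0)) gt[is.na(gt[, j]), j] <- cm[j]
  for (j in which(colSums(is.na(gc)) > 0)) gc[is.na(gc[, j]), j] <- cm[j]
  p <- colMeans(gt) / 2
  poly <- p > 0 & p < 1
  gt <- gt[, poly, drop = FALSE]; gc <- gc[, poly, drop = FALSE]
  p <- p[poly]
  wc_t <- colMeans(gt - 1)
  Wt <- sweep(gt - 1, 2, wc_t)
  Wc <- sweep(gc - 1, 2, wc_t)
  hc_t <- colMeans((gt == 1) * 1)
  Ht <- sweep((gt == 1) * 1, 2, hc_t)
  Hc <- sweep((gc == 1) * 1, 2, hc_t)
  denomA <- 2 * sum(p * (1 - p))
  denomD <- if (d_denominator == "shared") denomA else sum((2 * p * (1 - p))^2)
  list(A_tt = tcrossprod(Wt) / denomA, A_ct = tcrossprod(Wc, Wt) / denomA,
       D_tt = tcrossprod(Ht) / denomD, D_ct = tcrossprod(Hc, Ht) / denomD)
}

# conditional-expectation prediction: u_cand = K_ct (K_tt + jitter I)^-1 u_t
predict_from_blocks <- function(K_ct, K_tt, u_train, jitter = 1e-8) {
  n <- nrow(K_tt)
  drop(K_ct %*% solve(K_tt + diag(jitter * mean(diag(K_tt)), n), u_train))
}

#' Predict GEBVs for unphenotyped candidates
#'
#' Builds joint relationship matrices over training plus candidates and
#' takes the conditional expectation
#' u_cand = G_ct (G_tt + lambda I)^-1 u_train for the additive (and, when
#' fitted, dominance) components. An equivalent marker-effect back-solve
#' (`method = "marker"`) solves for per-marker effects from the training
#' BLUPs and applies them to the candidate coding; the two agree on
#' full-rank instances.
#'
#' @param fit `gblup_fit` trained on the training cohort.
#' @param train_geno,cand_geno geno_matrix (or dosage matrix) for training
#'   and candidate individuals on the identical marker panel.
#' @param method `"relationship"` (default) or `"marker"`.
#' @param d_denominator passed to [build_relationship_matrices()].
#' @return numeric GEBV per candidate (additive + dominance when fitted).
#' @export
predict_gebv <- function(fit, train_geno, cand_geno,
                         method = c("relationship", "marker"),
                         d_denominator = "shared") {
  method <- match.arg(method)
  gt <- if (inherits(train_geno, "geno_matrix")) train_geno$geno else as.matrix(train_geno)
  gc <- if (inherits(cand_geno, "geno_matrix")) cand_geno$geno else as.matrix(cand_geno)
  if (ncol(gt) != ncol(gc)) stop("marker panels differ between training and candidates")
  with_dom <- !is.null(fit$dominance_values)
  if (method == "relationship") {
    bl <- joint_blocks(gt, gc, d_denominator)
    pred <- predict_from_blocks(bl$A_ct, bl$A_tt, fit$gebv)
    if (with_dom)
      pred <- pred + predict_from_blocks(bl$D_ct, bl$D_tt,
                                         fit$dominance_values)
  } else {
    pred <- marker_backsolve(gt, gc, fit$gebv, coding = "additive")
    if (with_dom)
      pred <- pred + marker_backsolve(gt, gc, fit$dominance_values,
                                      coding = "dominance")
  }
  unname(pred)
}

# back-solve marker effects m = Z' (Z Z' + jitter)^-1 u on the centered
# training coding, then apply the same centering to candidates
marker_backsolve <- function(gt, gc, u, coding, jitter = 1e-8) {
  code <- function(g, centers) {
    z <- if (coding == "additive") g - 1 else (g == 1) * 1
    sweep(z, 2, centers)
  }
  zt_raw <- if (coding == "additive") gt - 1 else (gt == 1) * 1
  centers <- colMeans(zt_raw)
  Zt <- code(gt, centers)
  Zc <- code(gc, centers)
  G <- tcrossprod(Zt)
  m <- crossprod(Zt, solve(G + diag(jitter * mean(diag(G)), nrow(G)), u))
  drop(Zc %*% m)
}

#' Enumerate pseudo-combinations of inbred parent sets
#'
#' One in-silico F1 per (female, male) pair, so the combination count is
#' exactly the product of the parent-set sizes. Parents must be effectively
#' inbred: residual heterozygous sites up to `het_tol` (fraction) are
#' treated as missing, more is an error.
#'
#' @param females,males geno_matrix objects on the identical marker panel.
#' @param het_tol tolerated per-parent heterozygosity (default 0.02).
#' @param genotypes return the F1 dosage matrix too (memory: pairs x
#'   markers); set FALSE to enumerate only the pairing table.
#' @return list of class `pseudo_combinations`: `pairs` (data.frame female,
#'   male), `n`, and `geno` (F1 dosage matrix or NULL).
#' @export
enumerate_combinations <- function(females, males, het_tol = 0.02,
                                   genotypes = TRUE) {
  gf <- females$geno
  gm <- males$geno
  if (nrow(gf) == 0L || nrow(gm) == 0L) stop("empty parent set")
  if (ncol(gf) != ncol(gm)) stop("parent sets must share a marker panel")
  clean <- function(g, who) {
    het <- rowMeans(g == 1L, na.rm = TRUE)
    if (any(het > het_tol, na.rm = TRUE))
      stop(who, " parent(s) exceed the heterozygosity tolerance: ",
           paste(rownames(g)[which(het > het_tol)], collapse = ", "))
    g[g == 1L] <- NA_integer_
    g
  }
  gf <- clean(gf, "female")
  gm <- clean(gm, "male")
  pairs <- expand.grid(female = rownames(gf), male = rownames(gm),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  geno <- NULL
  if (genotypes) {
    fi <- match(pairs$female, rownames(gf))
    mi <- match(pairs$male, rownames(gm))
    geno <- (gf[fi, , drop = FALSE] + gm[mi, , drop = FALSE]) %/% 2L
    geno[is.na(gf[fi, , drop = FALSE]) | is.na(gm[mi, , drop = FALSE])] <- NA_integer_
    rownames(geno) <- paste(pairs$female, pairs$male, sep = "_x_")
  }
  structure(list(pairs = pairs, n = nrow(pairs), geno = geno),
            class = "pseudo_combinations")
}

#' Selection-index configuration
#'
#' Four yield-related traits are scored against the candidate set's own
#' GEBV percentiles (>80\%: 40, 60-80\%: 30, 40-60\%: 20, 20-40\%: 10,
#' <20\%: 0, right-closed bins); three agronomic traits are scored 40
#' inside their optimal range and 20 outside (defaults: heading date 80-90
#' days, plant height 115-125 cm, grain shape 3.0-3.4). The index sums the
#' seven scores; candidates at or above `high_score` are flagged.
#'
#' @param percentile_traits character vector of percentile-scored traits.
#' @param range_traits named list of `c(lo, hi)` ranges.
#' @param high_score flagging threshold (default 80).
#' @return list of class `selection_index_config`.
#' @export
selection_index_config <- function(
    percentile_traits = c("yield_per_plant", "seed_setting_rate",
                          "grain_number_per_panicle", "valid_panicle_number"),
    range_traits = list(heading_date = c(80, 90),
                        plant_height = c(115, 125),
                        grain_shape = c(3.0, 3.4)),
    high_score = 80) {
  for (r in range_traits) stopifnot(length(r) == 2L, r[1] < r[2])
  structure(list(percentile_traits = percentile_traits,
                 range_traits = range_traits, high_score = high_score),
            class = "selection_index_config")
}

#' Multi-trait selection index over a candidate set
#'
#' @param gebv data.frame of per-candidate GEBVs with one column per trait
#'   named in the config (plus optional id columns, carried through).
#' @param config [selection_index_config()].
#' @return the input with per-trait score columns (`score_<trait>`),
#'   `index`, and `high_score` flag appended. Candidates with any missing
#'   trait are dropped with a message.
#' @export
selection_index <- function(gebv, config = selection_index_config()) {
  traits <- c(config$percentile_traits, names(config$range_traits))
  miss_tr <- setdiff(traits, names(gebv))
  if (length(miss_tr)) stop("missing trait column(s): ", paste(miss_tr, collapse = ", "))
  ok <- stats::complete.cases(gebv[traits])
  if (any(!ok)) {
    message(sum(!ok), " candidate(s) excluded for missing trait GEBVs")
    gebv <- gebv[ok, , drop = FALSE]
  }
  out <- gebv
  for (tr in config$percentile_traits) {
    x <- gebv[[tr]]
    q <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
    score <- ifelse(x > q[4], 40,
                    ifelse(x > q[3], 30,
                           ifelse(x > q[2], 20,
                                  ifelse(x > q[1], 10, 0))))
    out[[paste0("score_", tr)]] <- score
  }
  for (tr in names(config$range_traits)) {
    r <- config$range_traits[[tr]]
    x <- gebv[[tr]]
    out[[paste0("score_", tr)]] <- ifelse(x >= r[1] & x <= r[2], 40, 20)
  }
  sc <- out[paste0("score_", traits)]
  out$index <- rowSums(sc)
  out$high_score <- out$index >= config$high_score
  out
}

#' Screen pseudo-combinations for sterility-locus genotypes
#'
#' A combination is flagged when its F1 would be homozygous for a
#' sterility-causing allele at any locus whose rule applies to the female
#' line's cytoplasm/system ("WA" for the rf3/rf4 wild-abortive restorers,
#' "two_line" for tms5). A locus missing in either parent leaves the flag
#' undetermined (NA) for that combination.
#'
#' @param combos `pseudo_combinations` with `geno` retained.
#' @param sterility_loci data.frame: `locus` (marker column index), `name`,
#'   `sterile_dosage` (0 or 2: the homozygous dosage causing sterility),
#'   `system` ("WA" or "two_line").
#' @param female_system named character vector mapping female id to system.
#' @return data.frame: pairs plus `sterile_flag` (TRUE / FALSE / NA) and a
#'   comma-separated `sterile_loci` column naming the triggering loci.
#' @export
screen_sterility <- function(combos, sterility_loci, female_system) {
  stopifnot(inherits(combos, "pseudo_combinations"), !is.null(combos$geno))
  sys <- female_system[combos$pairs$female]
  flag <- rep(FALSE, combos$n)
  undet <- rep(FALSE, combos$n)
  hits <- vector("list", combos$n)
  for (i in seq_len(nrow(sterility_loci))) {
    li <- sterility_loci$locus[i]
    applies <- !is.na(sys) & sys == sterility_loci$system[i]
    g <- combos$geno[, li]
    hom <- !is.na(g) & g == sterility_loci$sterile_dosage[i]
    undet <- undet | (applies & is.na(g))
    idx <- which(applies & hom)
    flag[idx] <- TRUE
    for (j in idx) hits[[j]] <- c(hits[[j]], sterility_loci$name[i])
  }
  data.frame(combos$pairs,
             sterile_flag = ifelse(flag, TRUE, ifelse(undet, NA, FALSE)),
             sterile_loci = vapply(hits, function(h)
               if (is.null(h)) "" else paste(h, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}
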