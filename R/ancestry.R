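#' Call indica-japonica differentiated SNPs from two reference panels
#'
#' A marker is retained when (1) at least `min_indica` indica accessions
#' share one genotype, (2) at least `min_japonica` japonica accessions share
#' one genotype, and (3) the major alleles of the two panels differ.
#' Missing panel genotypes are excluded from the counts.
#'
#' @param indica_panel,japonica_panel geno_matrix objects on the identical
#'   marker map.
#' @param min_indica,min_japonica majority thresholds; defaults 17 and 21
#'   assume panel sizes of 19 and 23.
#' @return data.frame (class `diff_panel`) with one row per retained marker:
#'   `marker` (column index into the shared map), `chrom`, `pos`,
#'   `indica_dosage` / `jap_dosage` (the major-allele dosage codes, 0 or 2),
#'   and the supporting counts `n_indica`, `n_japonica`.
#' @export
call_differentiated_snps <- function(indica_panel, japonica_panel,
                                     min_indica = 17L, min_japonica = 21L) {
  stopifnot(inherits(indica_panel, "geno_matrix"),
            inherits(japonica_panel, "geno_matrix"))
  if (nrow(indica_panel$geno) == 0L || nrow(japonica_panel$geno) == 0L)
    stop("empty reference panel")
  if (!isTRUE(all.equal(indica_panel$map[c("chrom", "pos")],
                        japonica_panel$map[c("chrom", "pos")])))
    stop("panels must share a marker map")
  gi <- indica_panel$geno
  gj <- japonica_panel$geno
  m <- ncol(gi)

  # per-marker modal genotype count and major-allele dosage, missing excluded
  modal <- function(g) {
    cnt0 <- colSums(g == 0L, na.rm = TRUE)
    cnt1 <- colSums(g == 1L, na.rm = TRUE)
    cnt2 <- colSums(g == 2L, na.rm = TRUE)
    top <- pmax(cnt0, cnt1, cnt2)
    # allele frequency of alt = (cnt1 + 2*cnt2) / (2 * non-missing)
    nn <- cnt0 + cnt1 + cnt2
    alt_f <- ifelse(nn > 0, (cnt1 + 2 * cnt2) / (2 * nn), NA_real_)
    major <- ifelse(alt_f > 0.5, 2L, 0L)
    major[!is.na(alt_f) & alt_f == 0.5] <- NA_integer_  # tied major allele
    list(top = top, major = major)
  }
  mi <- modal(gi)
  mj <- modal(gj)
  keep <- mi$top >= min_indica & mj$top >= min_japonica &
    !is.na(mi$major) & !is.na(mj$major) & mi$major != mj$major
  out <- data.frame(marker = which(keep),
                    chrom = indica_panel$map$chrom[keep],
                    pos = indica_panel$map$pos[keep],
                    indica_dosage = mi$major[keep],
                    jap_dosage = mj$major[keep],
                    n_indica = mi$top[keep],
                    n_japonica = mj$top[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_panel", "data.frame")
  out
}

#' Classify one sample at the differentiated loci
#'
#' Labels every panel marker as II (homozygous indica major), JJ (homozygous
#' japonica major), IJ (heterozygous) or missing.
#'
#' @param sample integer dosage vector on the full marker map the panel was
#'   called from.
#' @param panel `diff_panel` from [call_differentiated_snps()].
#' @return data.frame (class `ancestry_track`): `marker`, `chrom`, `pos`,
#'   `label` in \{"II", "IJ", "JJ", "missing"\}.
#' @export
classify_sites <- function(sample, panel) {
  stopifnot(inherits(panel, "diff_panel"))
  g <- sample[panel$marker]
  label <- rep("missing", nrow(panel))
  label[!is.na(g) & g == panel$indica_dosage] <- "II"
  label[!is.na(g) & g == panel$jap_dosage] <- "JJ"
  label[!is.na(g) & g == 1L] <- "IJ"
  out <- data.frame(marker = panel$marker, chrom = panel$chrom,
                    pos = panel$pos, label = label, stringsAsFactors = FALSE)
  class(out) <- c("ancestry_track", "data.frame")
  out
}

#' Sliding-window scan for japonica introgression
#'
#' Applies a `window`-SNP sliding window (1-SNP step) along each chromosome
#' of an ancestry track. A window is called homozygous-japonica when it
#' holds at least `min_hits` JJ labels, heterozygous-japonica when at least
#' `min_hits` IJ labels (missing labels count toward neither state). Per
#' state, the union of passing windows is reduced to maximal runs of covered
#' panel SNPs and adjacent same-state runs are combined. Where hom and het
#' coverage overlap near boundaries, each SNP is assigned to the state
#' supported by more covering windows, ties going to the heterozygous state.
#'
#' @param track `ancestry_track` from [classify_sites()].
#' @param window window length in panel SNPs (default 199).
#' @param min_hits minimum label count to call a window (default 120).
#' @return data.frame of segments: `chrom`, `start_idx` / `end_idx`
#'   (0-based half-open indices into the track), `start_bp` / `end_bp`
#'   (positions of the first and last covered SNP), `state`
#'   (`hom_japonica` / `het_japonica`), `n_windows` (supporting passing
#'   windows), `n_snps`.
#' @export
scan_introgression <- function(track, window = 199L, min_hits = 120L) {
  stopifnot(inherits(track, "ancestry_track"), window >= 1, min_hits >= 1)
  segs <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch, , drop = FALSE]
    k <- nrow(t_ch)
    if (k < window) next
    jj <- as.integer(t_ch$label == "JJ")
    ij <- as.integer(t_ch$label == "IJ")
    nw <- k - window + 1L
    hits_jj <- window_sums(jj, window)
    hits_ij <- window_sums(ij, window)
    pass_jj <- hits_jj >= min_hits
    pass_ij <- hits_ij >= min_hits
    cov_jj <- window_coverage(pass_jj, window, k)
    cov_ij <- window_coverage(pass_ij, window, k)
    # overlap resolution: state with more covering windows wins, tie -> het
    covered_jj <- cov_jj > 0 & cov_jj > cov_ij
    covered_ij <- cov_ij > 0 & cov_ij >= cov_jj
    segs[[length(segs) + 1L]] <- runs_to_segments(covered_jj, "hom_japonica",
                                                  t_ch, pass_jj, window)
    segs[[length(segs) + 1L]] <- runs_to_segments(covered_ij, "het_japonica",
                                                  t_ch, pass_ij, window)
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), start_bp = integer(),
                      end_bp = integer(), state = character(),
                      n_windows = integer(), n_snps = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start_idx, out$state), , drop = FALSE]
}

# rolling sums of x over a fixed window (length(x) - w + 1 values)
window_sums <- function(x, w) {
  cs <- c(0L, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

# how many passing windows cover each position 1..k
window_coverage <- function(pass, w, k) {
  cov <- integer(k)
  if (!any(pass)) return(cov)
  starts <- which(pass)
  d <- integer(k + 1L)
  for (s in starts) {
    d[s] <- d[s] + 1L
    d[min(s + w, k + 1L)] <- d[min(s + w, k + 1L)] - 1L
  }
  cumsum(d[seq_len(k)])
}

runs_to_segments <- function(covered, state, t_ch, pass, w) {
  if (!any(covered)) return(NULL)
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  win_starts <- which(pass)
  data.frame(chrom = t_ch$chrom[1L],
             start_idx = starts[keep] - 1L,
             end_idx = ends[keep],
             start_bp = t_ch$pos[starts[keep]],
             end_bp = t_ch$pos[ends[keep]],
             state = state,
             n_windows = vapply(keep, function(i)
               sum(win_starts <= ends[i] & win_starts + w - 1L >= starts[i]),
               integer(1)),
             n_snps = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Per-bin fraction of individuals carrying each introgression state
#'
#' @param segment_list list of segment data.frames (one per individual, as
#'   returned by [scan_introgression()]).
#' @param bins data.frame tiling the map: `chrom`, `start_bp`, `end_bp`
#'   (half-open on bp).
#' @return data.frame: bins with `frac_hom` and `frac_het` columns, the
#'   fraction of individuals whose segments of that state overlap the bin.
#' @export
summarize_introgression <- function(segment_list, bins) {
  if (length(segment_list) == 0L) stop("empty population")
  n <- length(segment_list)
  frac <- function(state) {
    sapply(seq_len(nrow(bins)), function(b) {
      hit <- vapply(segment_list, function(seg) {
        s <- seg[seg$state == state & seg$chrom == bins$chrom[b], , drop = FALSE]
        any(s$start_bp < bins$end_bp[b] & s$end_bp >= bins$start_bp[b])
      }, logical(1))
      mean(hit)
    })
  }
  cbind(bins, frac_hom = frac("hom_japonica"), frac_het = frac("het_japonica"))
}

#' Genome composition of one ancestry track
#'
#' @param track `ancestry_track`.
#' @return named numeric: fractions `II`, `IJ`, `JJ` over classified labels
#'   (summing to 1) plus `missing`, the fraction of unclassified labels.
#' @export
genome_composition <- function(track) {
  stopifnot(inherits(track, "ancestry_track"))
  lab <- track$label
  n_ok <- sum(lab != "missing")
  if (n_ok == 0L) stop("track is entirely missing")
  c(II = sum(lab == "II") / n_ok,
    IJ = sum(lab == "IJ") / n_ok,
    JJ = sum(lab == "JJ") / n_ok,
    missing = mean(lab == "missing"))
}

#' Write introgression segments as BED-like TSV
#'
#' Coordinates are 0-based half-open on bp (`start_bp - 1` to `end_bp`),
#' the BED convention.
#'
#' @param segment_list named list of segment data.frames (names = ids).
#' @param path output path.
#' @export
write_segments_bed <- function(segment_list, path) {
  rows <- lapply(names(segment_list), function(id) {
    s <- segment_list[[id]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(chrom = s$chrom, start = s$start_bp - 1L, end = s$end_bp,
               individual = id, state = s$state, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
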