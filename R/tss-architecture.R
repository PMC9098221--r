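# TSS subregion architecture: upstream/center/downstream triplets
# bracketing the -1/+1 nucleosomes and the NFR, per-region fold-change
# calls, decreased-TSS selection, and the five-cluster taxonomy.

#' Subregion offsets around a TSS
#'
#' Transcription-relative spans (bp) of the three quantification
#' regions: Upstream and Downstream bracket the canonical -1 and +1
#' nucleosome positions, Center the nucleosome-free region between
#' them.  Defaults: upstream (-300, -100), center (-100, +100),
#' downstream (+100, +300).
#'
#' @param upstream,center,downstream length-2 numeric spans `(from, to)`
#'   relative to the TSS; the three must be ordered, disjoint and of
#'   positive width.
#' @return Validated list of class `region_offsets`.
#' @export
region_offsets <- function(upstream = c(-300, -100),
                           center = c(-100, 100),
                           downstream = c(100, 300)) {
  spans <- list(upstream = upstream, center = center, downstream = downstream)
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2 || s[2] <= s[1]) {
      stop(sprintf("%s span must be (from, to) with to > from", nm),
           call. = FALSE)
    }
  }
  if (upstream[2] > center[1] || center[2] > downstream[1]) {
    stop("regions must be ordered and disjoint: upstream < center < downstream",
         call. = FALSE)
  }
  structure(spans, class = "region_offsets")
}

#' Upstream/Center/Downstream intervals for promoters
#'
#' Places the three subregions at their transcription-relative offsets,
#' mirrored on the minus strand and clamped at chromosome bounds.
#'
#' @param promoters data.frame with `chrom`, `tss`, `strand` (a promoter
#'   catalog row set).
#' @param offsets a [region_offsets()].
#' @param chrom_sizes optional named chromosome lengths for clamping.
#' @return Named list of three interval data.frames (`upstream`,
#'   `center`, `downstream`), rows aligned to `promoters`.
#' @export
define_regions <- function(promoters, offsets = region_offsets(),
                           chrom_sizes = NULL) {
  lapply(offsets, function(s) {
    oriented_interval(promoters$chrom, promoters$tss, promoters$strand,
                      s[1], s[2], chrom_sizes)
  })
}

#' Call the direction of an occupancy change
#'
#' With pseudocount-stabilized intensities `c = control + eps` and
#' `k = kd + eps`: `DECREASED` when `c/k >= fold_threshold`, `INCREASED`
#' when `k/c >= fold_threshold`, else `UNCHANGED`.
#'
#' @param control_intensity,kd_intensity non-negative intensities
#'   (vectorized).
#' @param params a [diff_params()].
#' @return Factor with levels `DECREASED`, `UNCHANGED`, `INCREASED`.
#' @export
call_change <- function(control_intensity, kd_intensity,
                        params = diff_params()) {
  stopifnot(all(control_intensity >= 0), all(kd_intensity >= 0))
  eps <- params$pseudocount
  cc <- control_intensity + eps
  kk <- kd_intensity + eps
  lab <- ifelse(cc == 0 & kk == 0, "UNCHANGED",
                ifelse(cc >= params$fold_threshold * kk, "DECREASED",
                       ifelse(kk >= params$fold_threshold * cc, "INCREASED",
                              "UNCHANGED")))
  factor(lab, levels = c("DECREASED", "UNCHANGED", "INCREASED"))
}

#' Five-cluster label from upstream/downstream change calls
#'
#' Fixed taxonomy of combinatorial occupancy changes:
#' (DEC, DEC) -> Cluster1; (DEC, UNCH) -> Cluster2 (upstream/-1
#' nucleosome loss); (UNCH, DEC) -> Cluster3; (DEC, INC) -> Cluster4;
#' (INC, DEC) -> Cluster5; every other combination -> UNCLUSTERED.
#' Swapping upstream and downstream maps Cluster2<->Cluster3 and
#' Cluster4<->Cluster5 with Cluster1 fixed.
#'
#' @param up,down change-call factors/vectors from [call_change()] for
#'   the upstream and downstream regions (same `diff_params`).
#' @return Factor with levels `Cluster1`..`Cluster5`, `UNCLUSTERED`.
#' @export
assign_cluster <- function(up, down) {
  up <- as.character(up); down <- as.character(down)
  key <- paste(up, down, sep = "|")
  map <- c("DECREASED|DECREASED" = "Cluster1",
           "DECREASED|UNCHANGED" = "Cluster2",
           "UNCHANGED|DECREASED" = "Cluster3",
           "DECREASED|INCREASED" = "Cluster4",
           "INCREASED|DECREASED" = "Cluster5")
  lab <- unname(map[key])
  lab[is.na(lab)] <- "UNCLUSTERED"
  factor(lab, levels = c(paste0("Cluster", 1:5), "UNCLUSTERED"))
}

#' Per-TSS region intensities, change calls and cluster labels
#'
#' Quantifies control and knockdown tracks over the three subregions of
#' every promoter, calls per-region changes, and assigns the
#' five-cluster taxonomy.  Tracks should be normalized to equal mass
#' before calling (see [normalize_track()]).
#'
#' @param catalog promoter catalog ([deduplicate_tss()]).
#' @param control_track,kd_track [signal_track()]s of remodeler
#'   occupancy in control and knockdown.
#' @param offsets a [region_offsets()].
#' @param params a [diff_params()].
#' @param chrom_sizes optional named chromosome lengths.
#' @return `catalog` with added columns `up_ctrl`, `up_kd`, `center_ctrl`,
#'   `center_kd`, `down_ctrl`, `down_kd`, `up_call`, `down_call`,
#'   `cluster`, plus `up_log2fc` / `down_log2fc` pseudocounted estimates.
#' @export
cluster_tss <- function(catalog, control_track, kd_track,
                        offsets = region_offsets(), params = diff_params(),
                        chrom_sizes = NULL) {
  regions <- define_regions(catalog, offsets, chrom_sizes)
  out <- catalog
  out$up_ctrl <- window_intensity(control_track, regions$upstream)
  out$up_kd <- window_intensity(kd_track, regions$upstream)
  out$center_ctrl <- window_intensity(control_track, regions$center)
  out$center_kd <- window_intensity(kd_track, regions$center)
  out$down_ctrl <- window_intensity(control_track, regions$downstream)
  out$down_kd <- window_intensity(kd_track, regions$downstream)
  out$up_call <- call_change(out$up_ctrl, out$up_kd, params)
  out$down_call <- call_change(out$down_ctrl, out$down_kd, params)
  out$up_log2fc <- log2_ratio(out$up_kd, out$up_ctrl, params)
  out$down_log2fc <- log2_ratio(out$down_kd, out$down_ctrl, params)
  out$cluster <- assign_cluster(out$up_call, out$down_call)
  out
}

#' Select TSSs with decreased occupancy
#'
#' A TSS counts as decreased when its change call is `DECREASED` in at
#' least one of the upstream/downstream regions (every cluster of the
#' taxonomy contains at least one decrease).  Dropping a promoter class
#' (e.g. H3K4me3-Low, whose occupancy is too low to call) is left to
#' the caller.
#'
#' @inheritParams cluster_tss
#' @return The [cluster_tss()] table restricted to decreased TSSs; each
#'   retained row carries one of `Cluster1`..`Cluster5`.
#' @export
select_decreased_tss <- function(catalog, control_track, kd_track,
                                 offsets = region_offsets(),
                                 params = diff_params(),
                                 chrom_sizes = NULL) {
  tab <- cluster_tss(catalog, control_track, kd_track, offsets, params,
                     chrom_sizes)
  keep <- tab$up_call == "DECREASED" | tab$down_call == "DECREASED"
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
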