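#' Build a pipeline configuration from a YAML file
#'
#' Versioned schema: top-level `version` (currently 1), `inputs`
#' (paths for `genes`, `h3k4me3`, `h3k27me3`, `brg1_control`,
#' `brg1_kd`, `atac_control`, `atac_kd`, `brg1_peaks`, `atac_peaks`,
#' optional `expression`; mark entries may be lists of replicate
#' paths), optional `out_dir`, and optional `params` overriding any
#' default threshold (`min_gene_length`, `coding_prefix`,
#' `upstream_bp`, `downstream_bp`, `low_quantile`, `high_quantile`,
#' `pseudocount`, `fold_threshold`, `offsets` with
#' `upstream`/`center`/`downstream` spans, `deg_p_max`, `deg_fc_min`,
#' `brg1_link_dist`, `atac_link_dist`, `assign_max_dist`,
#' `target_mass`).  Every default equals the analysis's standard
#' printed constant.
#'
#' @param path path to the YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$version) || y$version != 1) {
    stop("config must declare 'version: 1'", call. = FALSE)
  }
  need <- c("genes", "h3k4me3", "h3k27me3", "brg1_control", "brg1_kd",
            "atac_control", "atac_kd", "brg1_peaks", "atac_peaks")
  missing <- setdiff(need, names(y$inputs))
  if (length(missing)) {
    stop(sprintf("config inputs lack: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  prm <- y$params
  g <- function(nm, default) if (is.null(prm[[nm]])) default else prm[[nm]]
  off <- g("offsets", NULL)
  offsets <- if (is.null(off)) region_offsets() else {
    region_offsets(upstream = unlist(off$upstream),
                   center = unlist(off$center),
                   downstream = unlist(off$downstream))
  }
  pipeline_config(
    genes = y$inputs$genes,
    h3k4me3 = y$inputs$h3k4me3, h3k27me3 = y$inputs$h3k27me3,
    brg1_control = y$inputs$brg1_control, brg1_kd = y$inputs$brg1_kd,
    atac_control = y$inputs$atac_control, atac_kd = y$inputs$atac_kd,
    brg1_peaks = y$inputs$brg1_peaks, atac_peaks = y$inputs$atac_peaks,
    expression = y$inputs$expression,
    catalog = catalog_params(min_gene_length = g("min_gene_length", 2000),
                             coding_prefix = g("coding_prefix", "NM_"),
                             upstream_bp = g("upstream_bp", 500),
                             downstream_bp = g("downstream_bp", 1000)),
    classifier = classifier_params(low_quantile = g("low_quantile", 0.25),
                                   high_quantile = g("high_quantile", 0.75)),
    offsets = offsets,
    differential = diff_params(pseudocount = g("pseudocount", 0.25),
                               fold_threshold = g("fold_threshold", 1.5)),
    deg_p_max = g("deg_p_max", 0.05), deg_fc_min = g("deg_fc_min", 1.5),
    brg1_link_dist = g("brg1_link_dist", 2000),
    atac_link_dist = g("atac_link_dist", 500),
    assign_max_dist = g("assign_max_dist", 2000),
    target_mass = g("target_mass", 1e6),
    out_dir = y$out_dir
  )
}
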