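#' Classify genes as pericentromeric, subtelomeric or interstitial
#'
#' Gene position is its center (`floor((start + end) / 2)`). The distance to
#' the centromere is the distance to the nearest edge of the centromere
#' interval (0 when the center lies inside it); the distance to the telomere
#' is `min(center, length - center)`. A gene within `window` of the
#' centromere (boundary inclusive) is pericentromeric; otherwise, within
#' `window` of a telomere it is subtelomeric; otherwise interstitial. When a
#' gene is within the window of both landmarks the centromere takes
#' precedence, which on acrocentric chromosomes (centromere abutting
#' position 0) makes the first megabases pericentromeric rather than
#' subtelomeric.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end`.
#' @param chrom_map Tibble with `chrom`, `length`, `cen_start`, `cen_end`
#'   (centromere interval, 0-based).
#' @param window Distance window in bp (default 5e6, i.e. 5 Mb).
#' @return Tibble: `gene_id`, `region` (`pericentromeric` / `subtelomeric` /
#'   `interstitial`), `dist_centromere`, `dist_telomere`.
#' @export
#' @examples
#' map <- tibble::tibble(chrom = "1", length = 1e8,
#'                       cen_start = 5e7, cen_end = 5.1e7)
#' genes <- tibble::tibble(gene_id = c("a", "b", "c"), chrom = "1",
#'                         start = c(2e6, 4.6e7, 2e7), end = c(2.1e6, 4.61e7, 2.1e7))
#' classify_gene_region(genes, map)
classify_gene_region <- function(genes, chrom_map, window = 5e6) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "length", "cen_start", "cen_end") %in%
                  names(chrom_map)),
            window > 0)
  bad_cen <- chrom_map$cen_start < 0 | chrom_map$cen_start >= chrom_map$cen_end |
    chrom_map$cen_end > chrom_map$length
  if (any(bad_cen)) {
    stop("invalid centromere interval for chromosome(s): ",
         paste(chrom_map$chrom[bad_cen], collapse = ", "), call. = FALSE)
  }

  m <- match(genes$chrom, chrom_map$chrom)
  if (anyNA(m)) {
    stop("chromosome(s) missing from map: ",
         paste(unique(genes$chrom[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  center <- floor((genes$start + genes$end) / 2)
  len <- chrom_map$length[m]
  if (any(center < 0 | center >= len)) {
    bad <- which(center < 0 | center >= len)
    stop("gene center outside chromosome for: ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }

  cs <- chrom_map$cen_start[m]
  ce <- chrom_map$cen_end[m]
  dist_cen <- pmax(0, cs - center, center - ce)
  dist_tel <- pmin(center, len - center)

  tibble::tibble(
    gene_id = genes$gene_id,
    region = dplyr::case_when(
      dist_cen <= window ~ "pericentromeric",
      dist_tel <= window ~ "subtelomeric",
      TRUE ~ "interstitial"
    ),
    dist_centromere = dist_cen,
    dist_telomere = dist_tel
  )
}
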