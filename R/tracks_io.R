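#' Read a genome annotation table
#'
#' The annotation lists, per chromosome and in the order they should be
#' processed, the chromosome length and the centromere interval. Coordinates
#' are 0-based half-open. Chromosome names are normalized by stripping any
#' leading `"chr"`. The Y chromosome and the mitochondrial genome are not
#' part of the design and are dropped with a warning if present.
#'
#' @param path tab-separated file with header
#'   `chrom  length  cen_start  cen_end`.
#' @return data.frame of class `genome_annotation` with columns `chrom`
#'   (character), `length`, `cen_start`, `cen_end` (numeric, bp).
#' @seealso [grch37_annotation()] for the packaged GRCh37 build.
#' @export
read_genome_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "length", "cen_start", "cen_end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ann <- data.frame(
    chrom = normalize_chrom(df$chrom),
    length = as.numeric(df$length),
    cen_start = as.numeric(df$cen_start),
    cen_end = as.numeric(df$cen_end),
    stringsAsFactors = FALSE
  )
  excluded <- ann$chrom %in% c("Y", "M", "MT")
  if (any(excluded)) {
    warning("dropping chromosome(s) outside the design: ",
            paste(ann$chrom[excluded], collapse = ", "))
    ann <- ann[!excluded, , drop = FALSE]
  }
  if (anyNA(ann$length) || any(ann$length <= 0)) {
    stop("chromosome lengths must be positive numbers")
  }
  bad <- which(is.na(ann$cen_start) | is.na(ann$cen_end) |
                 ann$cen_start < 0 | ann$cen_end > ann$length |
                 ann$cen_start >= ann$cen_end)
  if (length(bad) > 0) {
    stop("centromere interval outside chromosome bounds for: ",
         paste(ann$chrom[bad], collapse = ", "))
  }
  if (anyDuplicated(ann$chrom)) stop("duplicated chromosome names")
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Packaged GRCh37 genome annotation
#'
#' Chromosome lengths and centromere intervals for GRCh37/hg19 chromosomes
#' 1-22 and X (the panel design excludes Y and the mitochondrial genome).
#'
#' @return `genome_annotation` data.frame with 23 rows.
#' @export
grch37_annotation <- function() {
  read_genome_annotation(
    system.file("extdata", "grch37_annotation.tsv", package = "gscar",
                mustWork = TRUE)
  )
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a per-bin BAF/LRR track
#'
#' Bins are genomic intervals (0-based half-open) carrying the median B
#' allele frequency of the SNPs in the bin and the log2 tumor/normal depth
#' ratio. A missing BAF (no informative SNP in the bin) is encoded as `NA`;
#' such bins still contribute to the LRR track.
#'
#' Bins are validated against the annotation (known chromosome, coordinates
#' within bounds, `start < end`, BAF within [0,1], no overlapping bins) and
#' returned sorted by annotation chromosome order and start position.
#'
#' @param path tab-separated file with header `chrom start end baf lrr`;
#'   `baf` may be `NA`.
#' @param annotation a [genome_annotation][read_genome_annotation] object.
#' @return data.frame of class `bin_track` with columns `chrom`, `start`,
#'   `end`, `baf`, `lrr`.
#' @export
read_track <- function(path, annotation) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "baf", "lrr")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("track file is missing column(s): ", paste(missing, collapse = ", "))
  }
  # data line i of the file is row i + 1 (header)
  line_no <- seq_len(nrow(df)) + 1L
  parse_num <- function(col, allow_na = FALSE) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !(allow_na & (is.na(raw) | raw %in% c("NA", "", ".")))
    if (any(bad)) {
      stop(sprintf("malformed %s value '%s' on line %d of %s",
                   col, raw[which(bad)[1]], line_no[which(bad)[1]], path))
    }
    val
  }
  track <- data.frame(
    chrom = normalize_chrom(df$chrom),
    start = parse_num("start"),
    end = parse_num("end"),
    baf = parse_num("baf", allow_na = TRUE),
    lrr = parse_num("lrr"),
    stringsAsFactors = FALSE
  )
  validate_track(track, annotation, line_no, path)
}

validate_track <- function(track, annotation, line_no = NULL, path = "track") {
  if (is.null(line_no)) line_no <- seq_len(nrow(track))
  unknown <- !(track$chrom %in% annotation$chrom)
  if (any(unknown)) {
    stop(sprintf("unknown chromosome '%s' on line %d of %s",
                 track$chrom[which(unknown)[1]],
                 line_no[which(unknown)[1]], path))
  }
  bad_baf <- !is.na(track$baf) & (track$baf < 0 | track$baf > 1)
  if (any(bad_baf)) {
    stop(sprintf("BAF out of [0,1] (%.4g) on line %d of %s",
                 track$baf[which(bad_baf)[1]],
                 line_no[which(bad_baf)[1]], path))
  }
  bad_coord <- track$start < 0 | track$start >= track$end |
    track$end > annotation$length[match(track$chrom, annotation$chrom)]
  if (any(bad_coord)) {
    stop(sprintf("bin coordinates outside chromosome bounds on line %d of %s",
                 line_no[which(bad_coord)[1]], path))
  }
  ord <- order(match(track$chrom, annotation$chrom), track$start)
  track <- track[ord, , drop = FALSE]
  # overlapping bins within a chromosome are a data error
  same_chrom <- track$chrom[-1] == track$chrom[-nrow(track)]
  if (nrow(track) > 1 &&
      any(same_chrom & track$start[-1] < track$end[-nrow(track)])) {
    stop("overlapping bins within a chromosome in ", path)
  }
  rownames(track) <- NULL
  class(track) <- c("bin_track", "data.frame")
  track
}

#' Construct a bin track from vectors
#'
#' In-memory counterpart of [read_track()]; applies the same validation and
#' sorting.
#'
#' @param chrom,start,end,baf,lrr per-bin vectors (see [read_track()]).
#' @param annotation a `genome_annotation`.
#' @return `bin_track` data.frame.
#' @export
bin_track <- function(chrom, start, end, baf, lrr, annotation) {
  track <- data.frame(chrom = normalize_chrom(chrom),
                      start = as.numeric(start), end = as.numeric(end),
                      baf = as.numeric(baf), lrr = as.numeric(lrr),
                      stringsAsFactors = FALSE)
  validate_track(track, annotation)
}

#' Write a bin track to a tab-separated file
#'
#' @param track `bin_track` data.frame.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

segment_columns <- c("chrom", "start", "end", "n_bins", "baf", "lrr",
                     "cn", "n_a", "n_b")

#' Write a segment list to a BED-like tab-separated file
#'
#' Columns: `chrom start end n_bins baf lrr cn n_a n_b`; coordinates are
#' 0-based half-open. Columns not yet present (e.g. integer copy numbers
#' before purity fitting) are written as `NA`.
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  out <- as.data.frame(segments)
  for (col in segment_columns) if (is.null(out[[col]])) out[[col]] <- NA
  out <- out[, segment_columns, drop = FALSE]
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a segment list written by [write_segments()]
#'
#' @param path input path.
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(segment_columns, names(df))
  if (length(missing) > 0) {
    stop("segment file is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$chrom <- normalize_chrom(df$chrom)
  df
}
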