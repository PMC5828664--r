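#' Read a BED file of genomic intervals
#'
#' Intervals are 0-based, half-open, as in the BED standard. Optional fourth
#' and fifth columns are kept as `name` and `score`. The table is sorted by
#' chromosome and start on read. Chromosome names are passed through verbatim
#' (no "chr" normalisation).
#'
#' @param path Path to a tab- or whitespace-separated BED file.
#' @return A `data.table` with columns `chrom`, `start`, `end` and any extra
#'   columns present (`name`, `score`, ...).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3L) stop("BED file must have at least 3 columns: ", path)
  extra <- c("name", "score")
  nm <- c("chrom", "start", "end",
          extra[seq_len(max(0L, min(ncol(dt) - 3L, 2L)))])
  if (ncol(dt) > 5L) nm <- c(nm, paste0("V", seq(6L, ncol(dt))))
  data.table::setnames(dt, seq_along(nm), nm)
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$end <= dt$start)
  if (length(bad)) {
    stop("malformed BED interval (end <= start) at line ", bad[1L],
         " of ", path)
  }
  data.table::setkeyv(dt, c("chrom", "start"))
  dt[]
}

#' Write intervals to a BED file
#'
#' @param x A `data.table`/`data.frame` with `chrom`, `start`, `end` columns
#'   (0-based half-open); extra columns are written after the first three.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  lead <- c("chrom", "start", "end")
  stopifnot(all(lead %in% names(x)))
  data.table::setcolorder(x, c(lead, setdiff(names(x), lead)))
  data.table::fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Convert a BED-convention table to a GRanges object
#'
#' Shifts 0-based half-open intervals to the 1-based closed convention used
#' by [GenomicRanges::GRanges].
#'
#' @param bed A table with `chrom`, `start`, `end` (0-based half-open).
#' @return A `GRanges` with any extra columns as metadata.
#' @export
bed_to_gr <- function(bed) {
  bed <- data.table::as.data.table(bed)
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
  extra <- setdiff(names(bed), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(bed[, extra, with = FALSE])
  }
  gr
}

#' Convert a GRanges object to a BED-convention data.table
#'
#' @param gr A `GRanges`.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open) and
#'   metadata columns.
#' @export
gr_to_bed <- function(gr) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) dt <- cbind(dt, data.table::as.data.table(as.data.frame(mc)))
  dt
}

#' Read a headered TSV table
#' @param path File path.
#' @return A `data.table`.
#' @export
read_table_tsv <- function(path) data.table::fread(path, sep = "\t")

#' Write a headered TSV table
#' @param x Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}

## merge overlapping/adjacent intervals within each chromosome
.merge_bed <- function(bed) {
  bed <- data.table::as.data.table(bed)[order(chrom, start)]
  bed[, grp := cumsum(c(1L, as.integer(start[-1] > cummax(end)[-.N]))),
      by = chrom]
  out <- bed[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  out[]
}
utils::globalVariables("grp")

## TRUE for each (chrom, pos) point lying inside any interval of `bed`
## (0-based half-open). findInterval stab on merged intervals.
.point_in_bed <- function(chrom, pos, bed) {
  m <- .merge_bed(bed)
  out <- logical(length(pos))
  for (cc in unique(chrom)) {
    tt <- m[chrom == cc]
    sel <- which(chrom == cc)
    if (!nrow(tt)) next
    i <- findInterval(pos[sel], tt$start)
    out[sel] <- i >= 1L & pos[sel] < tt$end[pmax(i, 1L)]
  }
  out
}
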