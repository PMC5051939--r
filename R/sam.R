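# SAM text I/O and read grouping.
#
# Records are plain lists with the eleven mandatory fields plus a named
# character vector of optional tags (name -> "TYPE:VALUE").  Coordinates in
# records stay 1-based as in SAM; the expanded candidate representation
# (expand.R) is 0-based half-open.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

parse_sam_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L) stop("malformed SAM line (fewer than 11 fields): ", line)
  tags <- character(0)
  if (length(f) > 11L) {
    extra <- f[-(1:11)]
    nm <- substr(extra, 1L, 2L)
    tags <- substring(extra, 4L)
    names(tags) <- nm
  }
  list(qname = f[1], flag = as.integer(f[2]), rname = f[3],
       pos = as.integer(f[4]), mapq = as.integer(f[5]), cigar = f[6],
       rnext = f[7], pnext = as.integer(f[8]), tlen = as.integer(f[9]),
       seq = f[10], qual = f[11], tags = tags)
}

format_sam_record <- function(rec) {
  base <- paste(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq, rec$cigar,
                rec$rnext, rec$pnext, rec$tlen, rec$seq, rec$qual, sep = "\t")
  if (length(rec$tags))
    base <- paste(c(base, paste0(names(rec$tags), ":", rec$tags)),
                  collapse = "\t")
  base
}

#' Get or set an optional SAM tag on a record
#'
#' @param rec a SAM record as returned by [read_sam()].
#' @param name two-letter tag name, e.g. `"MD"`.
#' @return `get_tag()` returns the tag value as a character scalar (without
#'   its type prefix), or `NA` if absent.
#' @examples
#' sam <- read_sam(system.file("extdata", "toy.sam", package = "remapq"))
#' get_tag(sam$records[[1]], "MD")
#' @export
get_tag <- function(rec, name) {
  v <- unname(rec$tags[name])
  if (is.na(v)) return(NA_character_)
  sub("^[A-Za-z]:", "", v)
}

#' @rdname get_tag
#' @param type one-letter SAM tag type (`"Z"`, `"i"`, `"f"`, ...).
#' @param value tag value.
#' @return `set_tag()` returns the modified record.
#' @export
set_tag <- function(rec, name, type, value) {
  rec$tags[name] <- paste0(type, ":", value)
  rec
}

#' Read and write SAM text files
#'
#' Minimal reader/writer for the SAM text format.  The whole file is parsed
#' into a list of records; optional tags are kept verbatim.  BAM input is not
#' read directly: convert with `samtools view -h` first.
#'
#' @param path file path (or, for `write_sam()`, output path).
#' @return `read_sam()` returns a list with elements `header` (character
#'   vector of `@`-lines) and `records` (list of record lists); class
#'   `sam_set`.
#' @examples
#' sam <- read_sam(system.file("extdata", "toy.sam", package = "remapq"))
#' length(sam$records)
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (any(is_hdr) && !all(which(is_hdr) == seq_len(sum(is_hdr))))
    stop("SAM header lines must precede all records")
  body <- lines[!is_hdr & nzchar(lines)]
  structure(list(header = lines[is_hdr],
                 records = lapply(body, parse_sam_line)),
            class = "sam_set")
}

#' @rdname read_sam
#' @param sam a `sam_set` (list with `header` and `records`).
#' @export
write_sam <- function(sam, path) {
  out <- c(sam$header, vapply(sam$records, format_sam_record, ""))
  writeLines(out, path)
  invisible(path)
}

#' @export
print.sam_set <- function(x, ...) {
  cat(sprintf("SAM set: %d header line(s), %d record(s)\n",
              length(x$header), length(x$records)))
  invisible(x)
}

sam_sort_order <- function(header) {
  so <- grep("^@HD\t.*\tSO:", header, value = TRUE)
  if (!length(so)) return(NA_character_)
  sub(".*\tSO:([^\t]+).*", "\\1", so[1])
}

#' Group name-sorted SAM records by read name
#'
#' Splits the records of a name-grouped (or name-sorted) SAM set into one
#' group per read name, preserving input order.  Grouping by name is the unit
#' over which posterior probabilities normalize, so the input must keep all
#' records of a read adjacent; a name that reappears after an intervening
#' different name, or a coordinate-sorted header, is a hard error rather than
#' a silent mis-grouping.
#'
#' @param sam a `sam_set` from [read_sam()].
#' @return A named list of lists of records, one element per read name.
#' @examples
#' sam <- read_sam(system.file("extdata", "toy.sam", package = "remapq"))
#' names(group_sam(sam))
#' @export
group_sam <- function(sam) {
  if (identical(sam_sort_order(sam$header), "coordinate"))
    stop("input is coordinate-sorted; name-sort it first ",
         "(e.g. samtools sort -n) so all candidates of a read are adjacent")
  qn <- vapply(sam$records, `[[`, "", "qname")
  if (!length(qn)) return(structure(list(), names = character(0)))
  grp_id <- cumsum(c(TRUE, qn[-1] != qn[-length(qn)]))
  run_names <- qn[!duplicated(grp_id)]
  dup <- unique(run_names[duplicated(run_names)])
  if (length(dup))
    stop("input is not name-grouped: read name '", dup[1],
         "' reappears after other reads; name-sort the input")
  stats::setNames(split(sam$records, factor(grp_id, levels = unique(grp_id))),
                  run_names)
}

append_pg_line <- function(header, cl = "remapq") {
  ver <- tryCatch(as.character(utils::packageVersion("remapq")),
                  error = function(e) "0.0")
  c(header, sprintf("@PG\tID:remapq\tPN:remapq\tVN:%s\tCL:%s", ver, cl))
}
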