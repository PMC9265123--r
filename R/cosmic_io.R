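#' Canonical mutation-type vocabulary
#'
#' The seven mutation types used in COSMIC structural-variant exports.
#' Interchromosomal rearrangements are always reported as `"unknown"`;
#' the six typed kinds occur only for intrachromosomal events.
#'
#' @return Character vector of the seven canonical mutation types.
#' @export
mutation_types <- function() {
  c("inverted orientation", "noninverted orientation", "inversion",
    "deletion", "tandem duplication", "insertion", "unknown")
}

#' Default logical-field to column-name mapping for breakpoint tables
#'
#' COSMIC export column names vary across releases, so the reader is
#' configuration-driven: each logical field names the column that holds it.
#'
#' @return Named list mapping logical fields (`sample`, `cancer_type`,
#'   `mutation_type`, `location_from`, `location_to`) to column names.
#' @export
cosmic_column_map <- function() {
  list(
    sample        = "Sample name",
    cancer_type   = "Primary site",
    mutation_type = "Mutation Type",
    location_from = "Location From",
    location_to   = "Location To"
  )
}

#' Normalize a chromosome token to an index in 1..24
#'
#' Accepts `"1"`..`"22"`, `"X"`, `"Y"`, optionally prefixed with `"chr"`
#' in any case. Mitochondrial and unplaced contigs fall outside the fixed
#' 24-node universe (22 autosomes plus X and Y) and are rejected.
#'
#' @param token Character vector of chromosome tokens.
#' @return Integer vector; `NA` marks a rejected token so callers can count
#'   skips rather than stop.
#' @examples
#' normalize_chromosome(c("chrX", "7", "MT"))
#' @export
normalize_chromosome <- function(token) {
  tok <- toupper(trimws(as.character(token)))
  tok <- sub("^CHR", "", tok)
  out <- rep(NA_integer_, length(tok))
  num <- suppressWarnings(as.integer(tok))
  ok  <- !is.na(num) & num >= 1 & num <= 22 & grepl("^[0-9]+$", tok)
  out[ok] <- num[ok]
  out[tok == "X"] <- 23L
  out[tok == "Y"] <- 24L
  out
}

#' Convert a chromosome index back to its token
#'
#' @param idx Integer vector in 1..24.
#' @return Character vector: `"1"`..`"22"`, `"X"`, `"Y"`.
#' @export
chromosome_token <- function(idx) {
  stopifnot(all(idx >= 1L & idx <= 24L, na.rm = TRUE))
  tok <- as.character(idx)
  tok[idx == 23L] <- "X"
  tok[idx == 24L] <- "Y"
  tok
}

# Parse "2:123..140" / "X:10..20" / bare "2" into chrom token and start position.
parse_location <- function(x) {
  x <- trimws(as.character(x))
  has_pos <- grepl(":", x, fixed = TRUE)
  chrom <- ifelse(has_pos, sub(":.*$", "", x), x)
  rest  <- ifelse(has_pos, sub("^[^:]*:", "", x), NA_character_)
  start <- suppressWarnings(as.numeric(sub("\\.\\..*$", "", rest)))
  list(chrom = chrom, pos = start)
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a COSMIC-style breakpoint table into rearrangement endpoint records
#'
#' Each row of the table is one chromosomal aberration: a pair of breakpoints
#' ("Location From", "Location To") with its sample name, primary site
#' (cancer-type label) and mutation type. Rows whose chromosome token does
#' not normalize into the 24-chromosome universe are skipped and counted.
#' Mutation-type strings outside the canonical vocabulary are coerced to
#' `"unknown"` (and counted); interchromosomal records are always typed
#' `"unknown"`, matching the COSMIC convention.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param column_map Mapping of logical field to column name; see
#'   [cosmic_column_map()].
#' @param delim Field delimiter; default inferred from the file extension
#'   (`.csv` is comma, anything else tab).
#' @return A data frame of records with columns `sample_id`, `cancer_type`,
#'   `chrom_from`, `chrom_to`, `pos_from`, `pos_to`, `mutation_type`, and an
#'   attribute `"skip_report"` (list with `n_rows`, `n_kept`, `n_skipped`,
#'   `n_type_coerced`).
#' @export
read_breakpoints <- function(path, column_map = cosmic_column_map(),
                             delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- infer_delim(path, delim)
  tab <- utils::read.delim(path, sep = delim, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(unlist(column_map), names(tab))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not present in header: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("empty breakpoint table: ", path)
    rec <- empty_records()
    attr(rec, "skip_report") <- list(n_rows = 0L, n_kept = 0L,
                                     n_skipped = 0L, n_type_coerced = 0L)
    return(rec)
  }
  from <- parse_location(tab[[column_map$location_from]])
  to   <- parse_location(tab[[column_map$location_to]])
  cf <- normalize_chromosome(from$chrom)
  ct <- normalize_chromosome(to$chrom)
  keep <- !is.na(cf) & !is.na(ct)

  mt <- trimws(tolower(tab[[column_map$mutation_type]]))
  coerced <- !(mt %in% mutation_types())
  mt[coerced] <- "unknown"

  rec <- data.frame(
    sample_id     = trimws(tab[[column_map$sample]])[keep],
    cancer_type   = trimws(tab[[column_map$cancer_type]])[keep],
    chrom_from    = cf[keep],
    chrom_to      = ct[keep],
    pos_from      = from$pos[keep],
    pos_to        = to$pos[keep],
    mutation_type = mt[keep],
    stringsAsFactors = FALSE
  )
  # interchromosomal events carry no typed mutation call
  inter <- rec$chrom_from != rec$chrom_to
  rec$mutation_type[inter] <- "unknown"

  report <- list(n_rows = nrow(tab), n_kept = nrow(rec),
                 n_skipped = sum(!keep), n_type_coerced = sum(coerced & keep))
  if (report$n_skipped > 0) {
    message(report$n_skipped, " row(s) skipped (chromosome outside 1-22, X, Y)")
  }
  attr(rec, "skip_report") <- report
  rec
}

empty_records <- function() {
  data.frame(sample_id = character(), cancer_type = character(),
             chrom_from = integer(), chrom_to = integer(),
             pos_from = numeric(), pos_to = numeric(),
             mutation_type = character(), stringsAsFactors = FALSE)
}

#' Write rearrangement endpoint records back to the tabular breakpoint format
#'
#' Inverse of [read_breakpoints()]: locations are serialized as
#' `"chrom:start..start"` (or a bare chromosome token when the position is
#' absent), so a write/read round trip reproduces the records exactly.
#'
#' @param records Record data frame as returned by [read_breakpoints()].
#' @param path Output path; delimiter inferred from extension.
#' @param column_map As in [read_breakpoints()].
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(records, path, column_map = cosmic_column_map(),
                              delim = NULL) {
  delim <- infer_delim(path, delim)
  fmt_loc <- function(chrom, pos) {
    tok <- chromosome_token(chrom)
    ifelse(is.na(pos), tok, paste0(tok, ":", pos, "..", pos))
  }
  out <- data.frame(
    a = records$sample_id,
    b = records$cancer_type,
    c = records$mutation_type,
    d = fmt_loc(records$chrom_from, records$pos_from),
    e = fmt_loc(records$chrom_to, records$pos_to),
    stringsAsFactors = FALSE
  )
  names(out) <- unlist(column_map[c("sample", "cancer_type", "mutation_type",
                                    "location_from", "location_to")])
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group endpoint records by sample
#'
#' All aberrations sharing a sample name belong to one tumor sample and will
#' generate one graph. Within-sample record order is preserved. A sample
#' carrying two different cancer-type labels violates the data model and is
#' an error.
#'
#' @param records Record data frame.
#' @return An object of class `sample_table`: a named list, one element per
#'   sample in first-appearance order, each a list with `sample_id`,
#'   `cancer_type` and `records` (the sample's rows).
#' @export
group_by_sample <- function(records) {
  if (nrow(records) == 0) {
    out <- structure(list(), class = "sample_table")
    return(out)
  }
  ids <- unique(records$sample_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- records[records$sample_id == id, , drop = FALSE]
    labs <- unique(rows$cancer_type)
    if (length(labs) > 1) {
      stop("sample '", id, "' carries conflicting cancer-type labels: ",
           paste(labs, collapse = ", "))
    }
    out[[id]] <- list(sample_id = id, cancer_type = labs, records = rows)
  }
  structure(out, class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  n_rec <- sum(vapply(x, function(s) nrow(s$records), integer(1)))
  cat("<sample_table>", length(x), "samples,", n_rec, "records\n")
  invisible(x)
}

#' Classify rearrangements as inter- or intrachromosomal
#'
#' A rearrangement within one chromosome (a self-loop in the graph encoding)
#' is intrachromosomal; one joining two different chromosomes is
#' interchromosomal.
#'
#' @param records Record data frame.
#' @return Character vector, one of `"inter"` or `"intra"` per record.
#' @export
classify_rearrangement <- function(records) {
  ifelse(records$chrom_from == records$chrom_to, "intra", "inter")
}
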