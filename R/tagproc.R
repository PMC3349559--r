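new_clean_tag_table <- function(tags, ledger, library) {
  structure(list(library = library, tags = tags, ledger = ledger),
            class = "clean_tag_table")
}

empty_ledger <- function() {
  c(raw = 0L, clean = 0L, adaptor_only = 0L, containing_N = 0L,
    low_quality = 0L, singleton_removed = 0L)
}

#' Filter raw tag reads into clean tags
#'
#' Classifies raw reads in a fixed order: adaptor-only or empty reads first,
#' then reads containing N, then malformed reads (wrong length, missing the
#' CATG prefix, or non-ACGT characters) which are counted as low quality.
#' Surviving reads are tallied per distinct tag sequence and, as a final
#' step, tags with a copy number below `min_copy` (default 2, i.e. tags seen
#' exactly once, probable sequencing errors) are removed and their reads
#' counted as `singleton_removed`.  Singleton removal never merges an error
#' tag into a frequent neighbour.
#'
#' The ledger satisfies
#' `raw = clean + adaptor_only + containing_N + low_quality +
#' singleton_removed` on every input.
#'
#' @param reads Character vector of raw reads (uppercase nucleotides), or a
#'   `sim_library`.
#' @param adaptors Non-empty character vector; a read equal to, or beginning
#'   with, any of these strings (or an empty read) is adaptor-only.
#' @param tag_length Expected tag length (default 21).
#' @param min_copy Minimum copy number a distinct tag must reach to be kept
#'   (default 2; use 1 to disable singleton removal).
#' @param library Library label carried through to reports.
#' @return An object of class `clean_tag_table`: list with `library`,
#'   `tags` (data frame `tag`, `count`, sorted by decreasing count) and the
#'   named integer `ledger`.
#' @export
filter_raw_tags <- function(reads, adaptors = tag_adaptors(),
                            tag_length = 21L, min_copy = 2L,
                            library = NA_character_) {
  if (inherits(reads, "sim_library")) {
    if (is.na(library)) library <- reads$library
    reads <- reads$reads
  }
  if (!length(adaptors)) stopf("adaptor list must be non-empty")
  reads <- as.character(reads)
  n <- length(reads)
  if (!n) {
    return(new_clean_tag_table(
      data.frame(tag = character(0), count = integer(0)),
      empty_ledger(), library))
  }
  is_ad <- reads == ""
  for (a in adaptors) is_ad <- is_ad | startsWith(reads, a)
  rest <- reads[!is_ad]
  has_n <- grepl("N", rest, fixed = TRUE)
  rest <- rest[!has_n]
  ok <- nchar(rest) == tag_length &
    startsWith(rest, "CATG") &
    !grepl("[^ACGT]", rest)
  tab <- table(rest[ok])
  keep <- tab >= min_copy
  if (any(keep)) {
    tags <- data.frame(tag = names(tab)[keep], count = as.integer(tab[keep]),
                       stringsAsFactors = FALSE)
    tags <- tags[order(-tags$count, tags$tag), , drop = FALSE]
    rownames(tags) <- NULL
  } else {
    tags <- data.frame(tag = character(0), count = integer(0))
  }
  ledger <- c(raw = n,
              clean = sum(tags$count),
              adaptor_only = sum(is_ad),
              containing_N = sum(has_n),
              low_quality = sum(!ok),
              singleton_removed = sum(as.integer(tab[!keep])))
  ledger <- vapply(ledger, as.integer, integer(1))
  new_clean_tag_table(tags, ledger, library)
}

#' @export
print.clean_tag_table <- function(x, ...) {
  cat("Clean tag table", if (!is.na(x$library)) paste0("[", x$library, "]"),
      ":", nrow(x$tags), "distinct tags,", x$ledger[["clean"]],
      "clean reads of", x$ledger[["raw"]], "raw\n")
  invisible(x)
}

#' Read a raw library from FASTQ or a tag/count TSV
#'
#' FASTQ files are parsed with Biostrings; a two-column `tag`/`count` TSV is
#' expanded back into one read per copy.
#'
#' @param path File path; format chosen by extension (`.fq`/`.fastq` versus
#'   anything else).
#' @return Character vector of reads.
#' @export
read_raw_library <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("tag", "count") %in% names(tab)))
      stopf("tag/count TSV must have columns 'tag' and 'count': %s", path)
    rep(tab$tag, tab$count)
  }
}

#' Write / read a clean tag table
#'
#' The tag/count pairs go to a TSV and the ledger to a JSON file alongside
#' (same path with extension `.ledger.json`).
#'
#' @param x A `clean_tag_table`.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_clean_tags <- function(x, path) {
  stopifnot(inherits(x, "clean_tag_table"))
  write.table(x$tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(library = x$library), as.list(x$ledger)),
                       paste0(path, ".ledger.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_clean_tags
#' @export
read_clean_tags <- function(path) {
  tags <- read.delim(path, stringsAsFactors = FALSE)
  lj <- paste0(path, ".ledger.json")
  ledger <- empty_ledger()
  library <- NA_character_
  if (file.exists(lj)) {
    l <- jsonlite::read_json(lj, simplifyVector = TRUE)
    library <- l$library %||% NA_character_
    for (nm in names(ledger)) ledger[[nm]] <- as.integer(l[[nm]] %||% 0L)
  } else {
    ledger[["raw"]] <- ledger[["clean"]] <- sum(tags$count)
  }
  new_clean_tag_table(tags, ledger, library)
}

#' Raw-read component accounting per library
#'
#' Tabulates, for each library, the raw read count and the count and
#' percentage (of raw) in each cleaning category, in the layout of a
#' per-library sequencing summary table.
#'
#' @param tables A `clean_tag_table` or a list of them.
#' @param digits Decimal places for percentages (default 2).
#' @return Data frame with one row per library: counts and `*_pct` columns.
#' @export
report_raw_components <- function(tables, digits = 2) {
  if (inherits(tables, "clean_tag_table")) tables <- list(tables)
  rows <- lapply(tables, function(ct) {
    L <- as.list(ct$ledger)
    pct <- function(v) if (L$raw > 0) round(100 * v / L$raw, digits) else 0
    data.frame(library = ct$library, raw = L$raw,
               clean = L$clean, clean_pct = pct(L$clean),
               adaptor_only = L$adaptor_only,
               adaptor_only_pct = pct(L$adaptor_only),
               containing_N = L$containing_N,
               containing_N_pct = pct(L$containing_N),
               low_quality = L$low_quality,
               low_quality_pct = pct(L$low_quality),
               singleton_removed = L$singleton_removed,
               singleton_removed_pct = pct(L$singleton_removed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a count with its percentage, e.g. "11769284 (98.64%)"
#'
#' @param count Integer count(s).
#' @param pct Percentage(s).
#' @param digits Decimal places.
#' @return Character vector.
#' @export
format_count_pct <- function(count, pct, digits = 2) {
  sprintf(paste0("%d (%.", digits, "f%%)"), count, pct)
}
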