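#' Build the reference tag index from a unigene set
#'
#' Every occurrence of CATG with at least 17 following bases, on either
#' strand of every unigene, yields one indexed 21-bp tag.  Tags spanning an
#' N are skipped.  A tag occurring in more than one gene is flagged
#' intrinsically ambiguous.  All sites are indexed (not only the 3'-most):
#' de novo unigenes have unknown orientation and may be fragmentary, so
#' strand and site rank are recorded for diagnostics.
#'
#' @param reference A named `DNAStringSet`, a `sim_reference`, a FASTA path,
#'   or a named character vector of sequences.
#' @param tag_length Tag length (default 21 = CATG + 17).
#' @return An object of class `tag_index`: list with `entries` (data frame
#'   `tag`, `gene`, `strand`, `start` on the strand-local sequence,
#'   `start_plus`/`end_plus` on the stored plus strand, `site_rank` from the
#'   strand-local 3' end), `ambiguous` (tags naming > 1 gene) and
#'   `gene_lengths` (named integer vector over all input genes).
#' @export
build_tag_index <- function(reference, tag_length = 21L) {
  if (inherits(reference, "sim_reference")) reference <- reference$sequences
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  nm <- names(reference)
  if (is.null(nm) || any(nm == ""))
    stopf("reference sequences must all be named")
  dup <- nm[duplicated(nm)]
  if (length(dup)) stopf("duplicate sequence id: %s", dup[1L])
  chars <- toupper(as.character(reference))
  w <- nchar(chars)
  parts <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") chars else revcomp(chars)
    hits <- gregexpr("CATG", s, fixed = TRUE)
    for (i in seq_along(s)) {
      st <- hits[[i]]
      st <- st[st > 0L]
      st <- st[st <= w[i] - tag_length + 1L]
      if (!length(st)) next
      tg <- substring(s[i], st, st + tag_length - 1L)
      keep <- !grepl("N", tg, fixed = TRUE)
      if (!any(keep)) next
      st <- st[keep]; tg <- tg[keep]
      start_plus <- if (str == "+") st else w[i] - st - (tag_length - 2L)
      parts[[length(parts) + 1L]] <- data.frame(
        tag = tg, gene = nm[i], strand = str, start = st,
        start_plus = start_plus, end_plus = start_plus + tag_length - 1L,
        site_rank = rank(-st, ties.method = "first"),
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(parts)) do.call(rbind, parts) else
    data.frame(tag = character(0), gene = character(0), strand = character(0),
               start = integer(0), start_plus = integer(0),
               end_plus = integer(0), site_rank = integer(0))
  rownames(entries) <- NULL
  pe <- unique(entries[c("tag", "gene")])
  tab <- table(pe$tag)
  ambiguous <- names(tab)[tab > 1L]
  structure(list(entries = entries, ambiguous = ambiguous,
                 gene_lengths = setNames(as.integer(w), nm),
                 tag_length = as.integer(tag_length)),
            class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat("Reference tag index:", nrow(x$entries), "sites,",
      length(unique(x$entries$tag)), "distinct tags over",
      length(x$gene_lengths), "genes (", length(x$ambiguous),
      "ambiguous tags )\n")
  invisible(x)
}

# distance-d substitution neighbourhood of fixed-length tags; the CATG
# prefix is enzymatically fixed and never varied.  Returns data frame
# (i = tag index, variant, last_pos = right-most substituted position).
tag_neighbors <- function(tags, d = 1L, fixed_prefix = 4L, tag_length = 21L,
                          from_pos = fixed_prefix + 1L) {
  positions <- seq.int(from_pos, tag_length)
  acc <- list()
  for (p in positions) {
    orig <- substr(tags, p, p)
    for (b in c("A", "C", "G", "T")) {
      keep <- which(orig != b)
      if (!length(keep)) next
      v <- tags[keep]
      substr(v, p, p) <- b
      acc[[length(acc) + 1L]] <- data.frame(i = keep, variant = v,
                                            last_pos = p,
                                            stringsAsFactors = FALSE)
    }
  }
  out <- if (length(acc)) do.call(rbind, acc) else
    data.frame(i = integer(0), variant = character(0), last_pos = integer(0))
  if (d >= 2L) {
    # second substitution strictly right of the first: enumerates each
    # distance-2 variant exactly once
    deeper <- lapply(split(out, out$last_pos), function(blk) {
      if (blk$last_pos[1L] >= tag_length) return(NULL)
      nb <- tag_neighbors(blk$variant, 1L, fixed_prefix, tag_length,
                          from_pos = blk$last_pos[1L] + 1L)
      if (!nrow(nb)) return(NULL)
      data.frame(i = blk$i[nb$i], variant = nb$variant,
                 last_pos = nb$last_pos, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(list(), deeper))
    if (is.null(out))
      out <- data.frame(i = integer(0), variant = character(0),
                        last_pos = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Map clean tags to the reference index with bounded mismatch
#'
#' Each distinct clean tag is assigned at its minimal Hamming distance not
#' exceeding `max_mismatch` (the CATG anchor is held invariant; mismatches
#' are sought by neighbourhood enumeration over the 17 variable positions).
#' Exact hits strictly dominate mismatch hits.  If the minimal-distance hits
#' name exactly one gene (any strand, any site) the tag's copies count to
#' that gene and to `unique_match`; hits naming several genes count to
#' `multi_position` and to no gene; tags with no hit are unmapped.  Multiple
#' sites within one gene count once to the gene.
#'
#' The ledger satisfies `total_mapped = perfect_match + mismatch_match =
#' unique_match + multi_position` and `total_clean = total_mapped +
#' unmapped` (all in reads).
#'
#' @param tags A `clean_tag_table` or a data frame with columns `tag`,
#'   `count`.
#' @param index A `tag_index` from [build_tag_index()].
#' @param max_mismatch Maximum substitutions tolerated (0, 1 or 2;
#'   default 1).
#' @return An object of class `tag_mapping`: list with `counts` (named
#'   integer vector over all reference genes, unique matches only),
#'   `ledger`, `placements` (data frame `gene`, `strand`, `start`, `end` in
#'   plus-strand coordinates, `tag`, `count`, `mismatch`), `assignments`
#'   (per distinct tag), `gene_lengths`, `library`.
#' @export
map_tags <- function(tags, index, max_mismatch = 1L) {
  library <- NA_character_
  if (inherits(tags, "clean_tag_table")) {
    library <- tags$library
    tags <- tags$tags
  }
  if (!all(c("tag", "count") %in% names(tags)))
    stopf("tags must carry columns 'tag' and 'count'")
  if (!max_mismatch %in% 0:2) stopf("max_mismatch must be 0, 1 or 2")
  ent <- index$entries
  tg <- tags$tag
  cnt <- as.integer(tags$count)
  D <- length(tg)
  utags <- unique(ent$tag)
  pe <- unique(ent[c("tag", "gene")])
  genes_by_tag <- split(pe$gene, pe$tag)
  rows_by_tag <- split(seq_len(nrow(ent)), ent$tag)

  dist <- rep(NA_integer_, D)
  assigned <- rep(NA_character_, D)
  n_genes_hit <- integer(D)
  hit_utags <- vector("list", D)

  if (D) {
    m0 <- match(tg, utags)
    hit0 <- which(!is.na(m0))
    for (j in hit0) {
      g <- genes_by_tag[[tg[j]]]
      dist[j] <- 0L
      n_genes_hit[j] <- length(g)
      if (length(g) == 1L) assigned[j] <- g
      hit_utags[[j]] <- tg[j]
    }
    for (d in seq_len(max_mismatch)) {
      rem <- which(is.na(dist))
      if (!length(rem)) break
      nb <- tag_neighbors(tg[rem], d, tag_length = index$tag_length)
      mm <- match(nb$variant, utags)
      ok <- !is.na(mm)
      if (!any(ok)) next
      by_i <- split(mm[ok], nb$i[ok])
      for (ii in names(by_i)) {
        j <- rem[as.integer(ii)]
        us <- utags[unique(by_i[[ii]])]
        g <- unique(unlist(genes_by_tag[us], use.names = FALSE))
        dist[j] <- d
        n_genes_hit[j] <- length(g)
        if (length(g) == 1L) assigned[j] <- g
        hit_utags[[j]] <- us
      }
    }
  }

  mapped <- !is.na(dist)
  uniq <- mapped & !is.na(assigned)
  ledger <- c(total_clean = sum(cnt),
              total_mapped = sum(cnt[mapped]),
              perfect_match = sum(cnt[mapped & dist == 0L]),
              mismatch_match = sum(cnt[mapped & dist > 0L]),
              unique_match = sum(cnt[uniq]),
              multi_position = sum(cnt[mapped & !uniq]),
              unmapped = sum(cnt[!mapped]))
  ledger <- vapply(ledger, as.integer, integer(1))

  counts <- setNames(integer(length(index$gene_lengths)),
                     names(index$gene_lengths))
  if (any(uniq)) {
    agg <- tapply(cnt[uniq], assigned[uniq], sum)
    counts[names(agg)] <- as.integer(agg)
  }

  placements <- data.frame(gene = character(0), strand = character(0),
                           start = integer(0), end = integer(0),
                           tag = character(0), count = integer(0),
                           mismatch = integer(0))
  if (any(uniq)) {
    pl <- lapply(which(uniq), function(j) {
      rows <- unlist(rows_by_tag[hit_utags[[j]]], use.names = FALSE)
      rows <- rows[ent$gene[rows] == assigned[j]]
      data.frame(gene = ent$gene[rows], strand = ent$strand[rows],
                 start = ent$start_plus[rows], end = ent$end_plus[rows],
                 tag = tg[j], count = cnt[j], mismatch = dist[j],
                 stringsAsFactors = FALSE)
    })
    placements <- do.call(rbind, pl)
    rownames(placements) <- NULL
  }

  assignments <- data.frame(tag = tg, count = cnt, distance = dist,
                            gene = assigned, n_genes = n_genes_hit,
                            stringsAsFactors = FALSE)
  structure(list(counts = counts, ledger = ledger, placements = placements,
                 assignments = assignments,
                 gene_lengths = index$gene_lengths,
                 max_mismatch = as.integer(max_mismatch), library = library),
            class = "tag_mapping")
}

#' @export
print.tag_mapping <- function(x, ...) {
  cat("Tag mapping", if (!is.na(x$library)) paste0("[", x$library, "]"), ":",
      x$ledger[["total_mapped"]], "of", x$ledger[["total_clean"]],
      "clean reads mapped (", x$ledger[["unique_match"]], "unique )\n")
  invisible(x)
}

#' Per-gene coverage by mapped tag footprints
#'
#' Coverage is the fraction of a gene's bases covered by at least one
#' mapped 21-bp tag footprint (union of intervals, both strands projected
#' onto plus-strand coordinates), in \[0, 1\].  The histogram bins expressed
#' genes (>= 1 mapped tag) by coverage deciles, and the summary statistic is
#' the fraction of expressed genes with coverage above one half.
#'
#' @param mapping A `tag_mapping` from [map_tags()].
#' @param gene_lengths Named lengths; defaults to those stored in `mapping`.
#' @return List of class `coverage_profile`: `genes` (data frame `gene`,
#'   `length`, `covered`, `coverage`), `histogram` (decile bin counts over
#'   expressed genes), `n_expressed`, `frac_over_half`.
#' @export
coverage_profile <- function(mapping, gene_lengths = mapping$gene_lengths) {
  pl <- mapping$placements
  covered <- setNames(integer(length(gene_lengths)), names(gene_lengths))
  if (nrow(pl)) {
    ir <- IRanges::IRanges(start = pl$start,
                           end = pmin(pl$end, gene_lengths[pl$gene]))
    grp <- factor(pl$gene, levels = unique(pl$gene))
    red <- IRanges::reduce(S4Vectors::split(ir, grp))
    cb <- sum(IRanges::width(red))
    covered[names(cb)] <- as.integer(cb)
  }
  genes <- data.frame(gene = names(gene_lengths),
                      length = as.integer(gene_lengths),
                      covered = covered,
                      coverage = covered / as.numeric(gene_lengths),
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  expressed <- genes$coverage > 0
  brk <- seq(0, 1, by = 0.1)
  hist <- table(cut(genes$coverage[expressed], breaks = brk,
                    include.lowest = FALSE, right = TRUE))
  histogram <- data.frame(bin = names(hist), n = as.integer(hist),
                          stringsAsFactors = FALSE)
  structure(list(genes = genes, histogram = histogram,
                 n_expressed = sum(expressed),
                 frac_over_half = if (any(expressed))
                   mean(genes$coverage[expressed] > 0.5) else NA_real_),
            class = "coverage_profile")
}

#' Mapping ledger summary across libraries
#'
#' One row per library with mapped/unmapped, perfect/mismatch and
#' unique/multi-position read counts and their percentages of total clean
#' reads, in the layout of a per-library mapping statistics table.
#'
#' @param mappings A `tag_mapping` or list of them.
#' @param digits Decimal places for percentages.
#' @return Data frame, one row per library.
#' @export
report_mapping <- function(mappings, digits = 2) {
  if (inherits(mappings, "tag_mapping")) mappings <- list(mappings)
  rows <- lapply(mappings, function(m) {
    L <- as.list(m$ledger)
    pct <- function(v) if (L$total_clean > 0)
      round(100 * v / L$total_clean, digits) else 0
    data.frame(library = m$library, total_clean = L$total_clean,
               total_mapped = L$total_mapped,
               total_mapped_pct = pct(L$total_mapped),
               perfect_match = L$perfect_match,
               perfect_match_pct = pct(L$perfect_match),
               mismatch_match = L$mismatch_match,
               mismatch_match_pct = pct(L$mismatch_match),
               unique_match = L$unique_match,
               unique_match_pct = pct(L$unique_match),
               multi_position = L$multi_position,
               multi_position_pct = pct(L$multi_position),
               unmapped = L$unmapped, unmapped_pct = pct(L$unmapped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
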