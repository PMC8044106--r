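#' Build or validate a multiplexing sample sheet
#'
#' A sample sheet maps inline tag pairs (5-nt forward, 7-nt reverse) to sample
#' identities. With 4 forward and 12 reverse tags a single run resolves up to
#' 48 replicate populations.
#'
#' @param forward_tags character vector of 5-nt tags.
#' @param reverse_tags character vector of 7-nt tags.
#' @param condition,incubation,mix,replicate,transfer metadata recycled across
#'   the tag grid (forward varies fastest).
#' @return a data.frame of class \code{sample_sheet} with columns
#'   \code{forward_tag, reverse_tag, sample_id, condition, incubation, mix,
#'   replicate, transfer}.
#' @export
make_sample_sheet <- function(forward_tags, reverse_tags,
                              condition = "planktonic", incubation = "2d",
                              mix = "A", replicate = NA_integer_,
                              transfer = 9L) {
  grid <- expand.grid(forward_tag = forward_tags, reverse_tag = reverse_tags,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  sheet <- data.frame(
    grid,
    sample_id = paste0("S", seq_len(n)),
    condition = rep_len(condition, n),
    incubation = rep_len(incubation, n),
    mix = rep_len(mix, n),
    replicate = rep_len(if (all(is.na(replicate))) seq_len(n) else replicate, n),
    transfer = rep_len(transfer, n),
    stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname make_sample_sheet
#' @param sheet a data.frame with at least forward_tag, reverse_tag, sample_id.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("forward_tag", "reverse_tag", "sample_id")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(sheet$forward_tag, sheet$reverse_tag)))
    stop("sample sheet: (forward_tag, reverse_tag) pairs must be unique")
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet: sample_id must be unique")
  if (length(unique(nchar(sheet$forward_tag))) != 1 ||
      length(unique(nchar(sheet$reverse_tag))) != 1)
    stop("sample sheet: tags must be fixed-length")
  if (nrow(sheet) > 48)
    stop("sample sheet: at most 48 samples per run (4 forward x 12 reverse)")
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' @rdname make_sample_sheet
#' @param path tab-separated file with a header row.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read.delim(path, stringsAsFactors = FALSE))
}

#' Demultiplex read pairs by exact inline tag prefixes
#'
#' Compares the 5-nt prefix of mate 1 and the 7-nt prefix of mate 2 against
#' the sheet's tag pairs. The default is exact matching (0 mismatches); a
#' tolerance can be configured, in which case a read is assigned only when
#' exactly one sheet row is within the tolerance on both tags.
#'
#' @param seq1,seq2 character vectors of mate sequences (parallel).
#' @param sheet a validated \code{sample_sheet}.
#' @param tag_mismatches allowed mismatches per tag (default 0).
#' @param swap_mates if TRUE, the 5-nt tag is looked for on mate 2 (orientation
#'   knob).
#' @return character vector of sample_ids, NA for tag-unmatched pairs.
#' @export
demultiplex <- function(seq1, seq2, sheet, tag_mismatches = 0L,
                        swap_mates = FALSE) {
  if (swap_mates) { tmp <- seq1; seq1 <- seq2; seq2 <- tmp }
  lf <- nchar(sheet$forward_tag[1])
  lr <- nchar(sheet$reverse_tag[1])
  p1 <- substr(seq1, 1L, lf)
  p2 <- substr(seq2, 1L, lr)
  if (tag_mismatches == 0) {
    key <- paste(p1, p2)
    idx <- match(key, paste(sheet$forward_tag, sheet$reverse_tag))
    return(sheet$sample_id[idx])
  }
  n <- length(seq1)
  nhit <- integer(n)
  hit <- integer(n)
  for (r in seq_len(nrow(sheet))) {
    ok <- str_hamming(p1, sheet$forward_tag[r]) <= tag_mismatches &
          str_hamming(p2, sheet$reverse_tag[r]) <= tag_mismatches
    nhit <- nhit + ok
    hit[ok] <- r
  }
  out <- rep(NA_character_, n)
  one <- nhit == 1L
  out[one] <- sheet$sample_id[hit[one]]
  out
}

# vectorised Hamming distance of many strings against one pattern
str_hamming <- function(x, pat) {
  L <- nchar(pat)
  d <- integer(length(x))
  for (i in seq_len(L)) {
    d <- d + (substr(x, i, i) != substr(pat, i, i))
  }
  d
}

#' Assign one read pair to a strain by exact barcode lookup
#'
#' Implements the study's matching rule: a pair is linked to a barcode if at
#' least one of its mates contains the barcode verbatim (100% identity over
#' its full length, as a contiguous substring, by default also on the reverse
#' complement). Exactly one distinct barcode anywhere across both mates gives
#' an assignment; two or more distinct barcodes give \code{ambiguous}; none
#' gives \code{unassigned}. The same barcode seen on both mates (or twice on
#' one mate) counts once.
#'
#' @param seq1,seq2 mate sequences (character scalars).
#' @param library a \code{barcode_library}.
#' @param rc also search reverse complements (default TRUE).
#' @return list with \code{category} in \{assigned, ambiguous, unassigned\}
#'   and \code{strain_id} (NA unless assigned).
#' @export
match_barcode <- function(seq1, seq2, library, rc = TRUE) {
  validate_barcode_library(library)
  hits <- barcode_hit_sets(Biostrings::DNAStringSet(seq1),
                           Biostrings::DNAStringSet(seq2), library, rc)[[1]]
  if (length(hits) == 0) {
    list(category = "unassigned", strain_id = NA_character_)
  } else if (length(hits) == 1) {
    list(category = "assigned", strain_id = library$strain_id[hits])
  } else {
    list(category = "ambiguous", strain_id = NA_character_)
  }
}

# distinct barcode indices found per read pair, across both mates and
# (optionally) their reverse complements
barcode_hit_sets <- function(r1, r2, library, rc = TRUE) {
  pd <- Biostrings::PDict(library$barcode)
  sets <- list(Biostrings::vwhichPDict(pd, r1),
               Biostrings::vwhichPDict(pd, r2))
  if (rc) {
    sets <- c(sets,
              list(Biostrings::vwhichPDict(pd, Biostrings::reverseComplement(r1)),
                   Biostrings::vwhichPDict(pd, Biostrings::reverseComplement(r2))))
  }
  n <- length(r1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- unique(unlist(lapply(sets, `[[`, i), use.names = FALSE))
  }
  out
}

#' Count barcodes per sample from paired FASTQ files
#'
#' Single pass over synchronized mates: each pair is demultiplexed by its
#' inline tags, then assigned to a strain by exact barcode lookup. Ambiguous
#' pairs (hits against multiple distinct barcodes) are excluded from strain
#' counts but tallied per sample, as are unassigned pairs; pairs whose tags
#' match no sheet row are tallied as tag-unmatched.
#'
#' @param r1_path,r2_path paired FASTQ files (plain or gzip).
#' @param library a \code{barcode_library} mapping barcodes to strains.
#' @param sheet a \code{sample_sheet}.
#' @param rc search reverse complements too (default TRUE).
#' @param tag_mismatches allowed mismatches per inline tag (default 0).
#' @param swap_mates orientation knob passed to [demultiplex()].
#' @return a \code{count_table}: list with \code{counts} (samples x strains
#'   integer matrix), \code{summary} (per-sample assigned / ambiguous /
#'   unassigned plus the run-level tag_unmatched), and \code{total_pairs}.
#' @export
count_barcodes <- function(r1_path, r2_path, library, sheet, rc = TRUE,
                           tag_mismatches = 0L, swap_mates = FALSE) {
  validate_barcode_library(library)
  sheet <- validate_sample_sheet(sheet)
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2))
    stop("count_barcodes(): R1 and R2 differ in read count (",
         length(r1), " vs ", length(r2), ")")
  id1 <- sub("/[12]$", "", sub(" .*", "", names(r1)))
  id2 <- sub("/[12]$", "", sub(" .*", "", names(r2)))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("count_barcodes(): desynchronized mates at record ", bad[1],
         " ('", id1[bad[1]], "' vs '", id2[bad[1]], "')")

  strains <- library$strain_id
  counts <- matrix(0L, nrow = nrow(sheet), ncol = length(strains),
                   dimnames = list(sheet$sample_id, strains))
  summ <- data.frame(sample_id = sheet$sample_id,
                     assigned = 0L, ambiguous = 0L, unassigned = 0L,
                     stringsAsFactors = FALSE)
  tag_unmatched <- 0L
  n <- length(r1)
  if (n > 0) {
    s1 <- as.character(r1)
    s2 <- as.character(r2)
    sample_of <- demultiplex(s1, s2, sheet, tag_mismatches, swap_mates)
    tag_unmatched <- sum(is.na(sample_of))
    keep <- which(!is.na(sample_of))
    if (length(keep)) {
      hits <- barcode_hit_sets(r1[keep], r2[keep], library, rc)
      nh <- lengths(hits)
      srow <- match(sample_of[keep], sheet$sample_id)
      one <- nh == 1L
      if (any(one)) {
        scol <- unlist(hits[one], use.names = FALSE)
        tab <- table(factor(srow[one], levels = seq_len(nrow(sheet))),
                     factor(scol, levels = seq_along(strains)))
        counts <- counts + as.integer(tab)
        dim(counts) <- c(nrow(sheet), length(strains))
        dimnames(counts) <- list(sheet$sample_id, strains)
      }
      summ$assigned   <- tabulate(srow[one], nbins = nrow(sheet))
      summ$ambiguous  <- tabulate(srow[nh >= 2L], nbins = nrow(sheet))
      summ$unassigned <- tabulate(srow[nh == 0L], nbins = nrow(sheet))
    }
  }
  structure(list(counts = counts, summary = summ,
                 tag_unmatched = tag_unmatched, total_pairs = n),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "strains;", x$total_pairs, "pairs (",
      sum(x$summary$assigned), "assigned,", sum(x$summary$ambiguous),
      "ambiguous,", sum(x$summary$unassigned), "unassigned,",
      x$tag_unmatched, "tag-unmatched )\n")
  invisible(x)
}

#' Write a count table: the matrix plus a per-sample summary
#' @param ct a \code{count_table}.
#' @param counts_path,summary_path output TSV paths.
#' @export
write_count_table <- function(ct, counts_path, summary_path = NULL) {
  m <- data.frame(sample_id = rownames(ct$counts), ct$counts,
                  check.names = FALSE)
  write.table(m, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- ct$summary
    s$tag_unmatched_total <- ct$tag_unmatched
    write.table(s, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
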