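#' Build the strain panel of single and double deletion genotypes
#'
#' Given a universe of regulator loci, constructs the full competition panel:
#' the wild type (no deletion), every single-locus deletion, and every
#' unordered pair of deletions. For the canonical 12-locus rap-phr universe
#' (rapA..rapK plus the plasmid-borne rapP) this yields 79 genotypes
#' (1 + 12 + 66).
#'
#' Strain labels follow the field's shorthand: "WT" for the wild type, the
#' locus suffix for singles (rapA -> "A"), and concatenated suffixes for pairs
#' (rapA+rapB -> "AB"). Ordering is deterministic: WT first, singles in
#' alphabetical order, pairs in lexicographic order.
#'
#' @param loci character vector of distinct locus names; defaults to the
#'   12-element rap-phr universe.
#' @return a data.frame of class \code{strain_panel} with columns
#'   \code{strain_id}, \code{locus1}, \code{locus2} (NA when absent) and
#'   \code{n_deleted}.
#' @examples
#' nrow(build_strain_panel())  # 79
#' @export
build_strain_panel <- function(loci = default_rap_loci()) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("build_strain_panel(): duplicate locus names")
  if (length(loci) < 1) stop("build_strain_panel(): need at least one locus")
  loci <- sort(loci)
  lab <- locus_label(loci)

  singles <- data.frame(strain_id = lab, locus1 = loci, locus2 = NA_character_,
                        n_deleted = 1L, stringsAsFactors = FALSE)
  if (length(loci) >= 2) {
    pr <- t(utils::combn(seq_along(loci), 2))
    sep <- if (all(nchar(lab) == 1)) "" else "_"
    pairs <- data.frame(
      strain_id = paste(lab[pr[, 1]], lab[pr[, 2]], sep = sep),
      locus1 = loci[pr[, 1]], locus2 = loci[pr[, 2]],
      n_deleted = 2L, stringsAsFactors = FALSE)
  } else {
    pairs <- singles[0, ]
  }
  wt <- data.frame(strain_id = "WT", locus1 = NA_character_,
                   locus2 = NA_character_, n_deleted = 0L,
                   stringsAsFactors = FALSE)
  panel <- rbind(wt, singles, pairs)
  rownames(panel) <- NULL
  class(panel) <- c("strain_panel", "data.frame")
  panel
}

#' @rdname build_strain_panel
#' @export
default_rap_loci <- function() {
  c(paste0("rap", LETTERS[1:11]), "rapP")
}

locus_label <- function(loci) {
  ifelse(grepl("^rap", loci), sub("^rap", "", loci), loci)
}

#' Generate a barcode library with a minimum pairwise Hamming distance
#'
#' Draws random fixed-length nucleotide barcodes by rejection sampling: a
#' candidate is kept only if it is at least \code{min_hamming} substitutions
#' away from every barcode already accepted. Mirrors the random 12-bp tags
#' integrated at the amyE locus of each competing strain.
#'
#' @param n number of barcodes.
#' @param length barcode length in nucleotides (default 12).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @param seed integer seed; the draw is reproducible.
#' @param max_attempts rejection-sampling budget before giving up.
#' @return a \code{barcode_library}: data.frame with columns \code{barcode},
#'   \code{strain_id} (NA until assigned), plus attributes \code{length} and
#'   \code{min_pairwise_hamming}.
#' @export
generate_barcodes <- function(n, length = 12, min_hamming = 3, seed = 1L,
                              max_attempts = 1000L * n) {
  if (min_hamming < 1) stop("generate_barcodes(): min_hamming must be >= 1")
  if (n > 4^length)
    stop("generate_barcodes(): infeasible, n exceeds 4^length")
  if (min_hamming > length)
    stop("generate_barcodes(): infeasible, min_hamming exceeds barcode length")
  set.seed(seed)
  accepted <- character(0)
  acc_mat <- NULL
  attempts <- 0L
  while (length(accepted) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("generate_barcodes(): infeasible (n=", n, ", length=", length,
           ", min_hamming=", min_hamming, ") after ", max_attempts,
           " attempts")
    cand <- random_dna(1, length)
    cv <- strsplit(cand, "")[[1]]
    if (!is.null(acc_mat)) {
      d <- rowSums(acc_mat != matrix(cv, nrow(acc_mat), length, byrow = TRUE))
      if (any(d < min_hamming)) next
    }
    accepted <- c(accepted, cand)
    acc_mat <- rbind(acc_mat, cv)
  }
  lib <- data.frame(barcode = accepted, strain_id = NA_character_,
                    stringsAsFactors = FALSE)
  attr(lib, "length") <- as.integer(length)
  attr(lib, "min_pairwise_hamming") <- min_pairwise_hamming(accepted)
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

#' Assign barcodes to a strain panel
#'
#' @param library a \code{barcode_library} with at least as many entries as
#'   the panel has strains.
#' @param panel a \code{strain_panel}.
#' @return the library restricted to the panel, with \code{strain_id} filled
#'   in (injective: one barcode per strain).
#' @export
assign_barcodes <- function(library, panel) {
  if (nrow(library) < nrow(panel))
    stop("assign_barcodes(): fewer barcodes than strains")
  lib <- library[seq_len(nrow(panel)), , drop = FALSE]
  lib$strain_id <- panel$strain_id
  attr(lib, "length") <- attr(library, "length")
  attr(lib, "min_pairwise_hamming") <- min_pairwise_hamming(lib$barcode)
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

validate_barcode_library <- function(library) {
  bc <- library$barcode
  if (anyDuplicated(bc)) stop("barcode library: barcodes not unique")
  if (length(unique(nchar(bc))) != 1)
    stop("barcode library: heterogeneous barcode lengths")
  if (!all(grepl("^[ACGT]+$", bc)))
    stop("barcode library: barcodes must be over {A,C,G,T}")
  ids <- library$strain_id[!is.na(library$strain_id)]
  if (anyDuplicated(ids)) stop("barcode library: strain_id mapping not injective")
  invisible(TRUE)
}

#' Reject libraries whose barcodes collide with the fixed amplicon context
#'
#' A barcode occurring inside the tag/flank sequence (or its reverse
#' complement) would create spurious hits in every read; such libraries are
#' rejected at construction time.
#'
#' @param library a \code{barcode_library}.
#' @param design an \code{amplicon_design}.
#' @export
validate_library_context <- function(library, design) {
  ctx <- c(design$forward_tag, design$left_flank, design$right_flank,
           design$reverse_tag)
  ctx <- paste(c(ctx, revcomp(ctx)), collapse = "N")
  hit <- vapply(library$barcode, function(b) grepl(b, ctx, fixed = TRUE),
                logical(1))
  if (any(hit))
    stop("barcode library: barcode(s) ",
         paste(library$barcode[hit], collapse = ", "),
         " occur inside the fixed amplicon context")
  invisible(TRUE)
}

#' Read / write a barcode library as a tab-separated table
#' @param path file path.
#' @param library a \code{barcode_library}.
#' @export
write_barcode_library <- function(library, path) {
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_library
#' @export
read_barcode_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "strain_id") %in% names(lib)))
    stop("barcode library file must have columns barcode, strain_id")
  attr(lib, "length") <- unique(nchar(lib$barcode))[1]
  attr(lib, "min_pairwise_hamming") <- min_pairwise_hamming(lib$barcode)
  class(lib) <- c("barcode_library", "data.frame")
  validate_barcode_library(lib)
  lib
}
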