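# Independent oracles and small fixtures shared across test files.
# Everything here is deliberately naive and implemented without touching the
# package's own code paths (own reverse complement, own substring scan, own
# ANOVA decomposition), so that agreement is evidence, not tautology.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# naive all-barcodes x all-positions scan; returns category and strain
oracle_assign <- function(seq1, seq2, library, rc = TRUE) {
  targets <- c(seq1, seq2)
  if (rc) targets <- c(targets, oracle_revcomp(c(seq1, seq2)))
  found <- character(0)
  for (b in library$barcode) {
    for (s in targets) {
      hit <- FALSE
      L <- nchar(b)
      for (p in seq_len(max(nchar(s) - L + 1, 0))) {
        if (substr(s, p, p + L - 1) == b) { hit <- TRUE; break }
      }
      if (hit) { found <- c(found, b); break }
    }
  }
  found <- unique(found)
  if (length(found) == 0) {
    list(category = "unassigned", strain_id = NA_character_)
  } else if (length(found) == 1) {
    list(category = "assigned",
         strain_id = library$strain_id[match(found, library$barcode)])
  } else {
    list(category = "ambiguous", strain_id = NA_character_)
  }
}

# coordinate-space one-way ANOVA decomposition (Euclidean PERMANOVA oracle)
oracle_permanova_F <- function(X, g) {
  X <- as.matrix(X)
  g <- as.factor(g)
  gm <- colMeans(X)
  ss_total <- sum(sweep(X, 2, gm)^2)
  ss_within <- 0
  for (lev in levels(g)) {
    sub <- X[g == lev, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  df_b <- nlevels(g) - 1
  df_w <- nrow(X) - nlevels(g)
  list(F = ((ss_total - ss_within) / df_b) / (ss_within / df_w),
       r2 = (ss_total - ss_within) / ss_total)
}

# all n! orderings, written independently of the package's enumerator
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  prev <- oracle_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[prev], nrow(prev)))
    out <- rbind(out, block)
  }
  out
}

# fixed tiny library: four 8-mers, pairwise distant, no context collisions
tiny_library <- function() {
  # chosen so that no barcode is a palindrome or the reverse complement of
  # another (RC search must not create cross-hits)
  lib <- data.frame(
    barcode = c("AACCGTAA", "GGTTACGG", "ACGTCAGT", "TTGACTCC"),
    strain_id = c("WT", "A", "B", "AB"),
    stringsAsFactors = FALSE)
  class(lib) <- c("barcode_library", "data.frame")
  lib
}

tiny_design <- function() {
  amplicon_design(forward_tag = "ACGTC", reverse_tag = "TGCAGTC",
                  left_flank = "GATCC", right_flank = "CTGGA",
                  read_length = 30L, barcode_length = 8L)
}

# deterministic panel + 12-bp library for pipeline tests
full_fixture <- function(seed = 11L) {
  panel <- build_strain_panel()
  lib <- assign_barcodes(generate_barcodes(79, 12, 3, seed = seed), panel)
  design <- amplicon_design()
  validate_library_context(lib, design)
  list(panel = panel, lib = lib, design = design)
}
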