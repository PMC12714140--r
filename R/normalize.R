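SUPPORTED_CONTIGS <- c(as.character(1:22), "X")

#' Normalize a contig name
#'
#' Accepts \code{"chr1"}/\code{"1"} style aliases and returns the bare name
#' (\code{"1"}..\code{"22"}, \code{"X"}), or \code{NA} for contigs outside the
#' set the pipeline assesses (variants are prioritized for chromosomes 1-22
#' and X only; mitochondrial and alternate contigs are dropped).
#'
#' @param contig Character vector of contig names.
#' @return Character vector with unsupported contigs set to \code{NA}.
#' @export
normalize_contig <- function(contig) {
  x <- sub("^chr", "", as.character(contig), ignore.case = TRUE)
  x[!(x %in% SUPPORTED_CONTIGS)] <- NA_character_
  x
}

#' Normalize a small variant to its minimal left-aligned representation
#'
#' Trims shared suffix/prefix bases and, for indels, shifts the allele to the
#' leftmost admissible position (supplying one shared anchor base, VCF style).
#' Left-shifting through a repeat run requires reference sequence context;
#' pass it via \code{ref_seq}. SNVs and MNVs never need it. The operation is
#' idempotent, so coordinate-and-allele matching against inclusion and
#' exclusion lists is well defined.
#'
#' @param contig Contig name (aliases accepted).
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Reference and alternate allele strings over A/C/G/T.
#' @param ref_seq Optional reference context: a single string whose first
#'   character sits at coordinate \code{ref_seq_offset}.
#' @param ref_seq_offset 1-based coordinate of \code{substr(ref_seq, 1, 1)}.
#' @return A list of class \code{"nbs_variant"} with fields \code{contig},
#'   \code{pos}, \code{ref}, \code{alt} and \code{variant_class} (one of
#'   \code{"snv"}, \code{"indel"}, \code{"mnv"}).
#' @examples
#' normalize_variant("chr1", 100, "A", "T")
#' normalize_variant("1", 100, "TC", "TG")  # shared prefix trimmed
#' @export
normalize_variant <- function(contig, pos, ref, alt,
                              ref_seq = NULL, ref_seq_offset = 1L) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop("malformed alleles (non-ACGT): ref='", ref, "' alt='", alt, "'")
  }
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("pos must be a positive integer")
  if (ref == alt) {
    stop("degenerate variant: ref and alt are identical ('", ref, "')")
  }
  base_at <- function(p) {
    if (is.null(ref_seq)) {
      stop("left-aligning this indel requires reference context (ref_seq)")
    }
    i <- p - as.integer(ref_seq_offset) + 1L
    if (i < 1L || i > nchar(ref_seq)) {
      stop("reference context does not cover position ", p)
    }
    toupper(substr(ref_seq, i, i))
  }
  # vt-style normalization: truncate shared trailing bases, extending left
  # from the reference when an allele would become empty ...
  repeat {
    le_r <- nchar(ref); le_a <- nchar(alt)
    if (le_r > 0L && le_a > 0L &&
        substr(ref, le_r, le_r) == substr(alt, le_a, le_a)) {
      # trimming the shared trailing base may empty an allele; that needs a
      # left extension, which is impossible at the start of the contig —
      # there the anchored representation is already minimal
      if ((le_r == 1L || le_a == 1L) && pos == 1L) break
      ref <- substr(ref, 1L, le_r - 1L)
      alt <- substr(alt, 1L, le_a - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- base_at(pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  # ... then drop shared leading bases while both alleles keep >= 1 base.
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  ctg <- normalize_contig(contig)
  structure(
    list(contig = ctg, pos = pos, ref = ref, alt = alt,
         variant_class = variant_class(ref, alt)),
    class = "nbs_variant")
}

#' Classify a (ref, alt) allele pair
#'
#' @param ref,alt Allele strings (assumed minimal).
#' @return \code{"snv"}, \code{"mnv"} (equal lengths > 1) or \code{"indel"}.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "snv", "mnv"), "indel")
}

#' @export
print.nbs_variant <- function(x, ...) {
  cat(sprintf("<variant %s:%d %s>%s [%s]\n", x$contig, x$pos, x$ref, x$alt,
              x$variant_class))
  invisible(x)
}

#' Decompose a multinucleotide variant into its component SNVs
#'
#' Emits one normalized SNV per position at which the reference and alternate
#' alleles differ. Used for allele-frequency lookups: the frequency filter on
#' an MNV compares the minimum allele frequency of the decomposed variants.
#'
#' @param v An \code{nbs_variant} with \code{variant_class == "mnv"}.
#' @return List of \code{nbs_variant} objects, each an SNV, ordered by
#'   position; substituting them jointly reconstructs the MNV.
#' @examples
#' mnv <- normalize_variant("2", 50, "AG", "TC")
#' decompose_mnv(mnv)
#' @export
decompose_mnv <- function(v) {
  stopifnot(inherits(v, "nbs_variant"))
  if (v$variant_class != "mnv") {
    stop("decompose_mnv expects an MNV, got ", v$variant_class)
  }
  rb <- strsplit(v$ref, "")[[1]]
  ab <- strsplit(v$alt, "")[[1]]
  idx <- which(rb != ab)
  lapply(idx, function(i) {
    normalize_variant(v$contig, v$pos + i - 1L, rb[i], ab[i])
  })
}

#' Build the coordinate-and-allele key used for list matching
#'
#' @param contig,pos,ref,alt Vectors describing normalized variants.
#' @return Character vector \code{"contig:pos:ref:alt"}.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Canonicalize a predicted protein change for string matching
#'
#' Strips the \code{"p."} prefix and parentheses and normalizes the
#' termination symbol so that string equality defines protein matching
#' (three-letter amino-acid notation, e.g. \code{"Arg100Ter"}).
#'
#' @param x Character vector of protein-change notations (NA allowed).
#' @return Canonical character vector; empty strings become \code{NA}.
#' @export
normalize_protein_change <- function(x) {
  y <- as.character(x)
  y <- gsub("[()]", "", sub("^p\\.", "", trimws(y)))
  y <- gsub("\\*$", "Ter", y)
  y[!nzchar(y) | is.na(y)] <- NA_character_
  y
}
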