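# Readers/writers for the formats the pipeline touches. All genomic
# coordinates are 1-based inclusive internally (VCF convention); BED-style
# inputs are converted here, on read, and nowhere else.

CSQ_FIELDS <- c("Gene", "Transcript", "Consequence", "Impact",
                "ProteinChange", "Flags", "CdsLength")

empty_calls <- function() {
  data.frame(sample_id = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), variant_class = character(),
             filter = character(), zygosity = character(),
             phase_set = character(), haplotype_index = integer(),
             key = character(), stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(key = character(), gene = character(), transcript = character(),
             consequence = character(), impact = character(),
             protein_change = character(), flags = character(),
             cds_length = integer(), stringsAsFactors = FALSE)
}

#' Read an annotated small-variant VCF
#'
#' Reads a per-sample or multi-sample VCF, splits multi-allelic records,
#' normalizes each allele (minimal left-aligned representation) and drops
#' records on contigs other than 1-22/X. Per-transcript annotations are taken
#' from a VEP-style delimited \code{CSQ} INFO field
#' (\code{Gene|Transcript|Consequence|Impact|ProteinChange|Flags|CdsLength},
#' terms within a field separated by \code{&}) or, alternatively, from a
#' sidecar annotation table supplied to the engine separately.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param ref_seq,ref_seq_offset Optional reference context forwarded to
#'   \code{\link{normalize_variant}} (only needed to left-shift indels
#'   emitted in a non-normalized form).
#' @return A list of class \code{"nbs_vcf"}: \code{$calls}, a data frame of
#'   per-sample genotype calls (sample_id, contig, pos, ref, alt,
#'   variant_class, filter, zygosity, phase_set, haplotype_index, key), and
#'   \code{$annotations}, a per-transcript annotation data frame keyed like
#'   the calls. Records with missing GT are skipped with a warning.
#' @export
read_small_variant_vcf <- function(path, ref_seq = NULL, ref_seq_offset = 1L) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(vcf) || nrow(vcf@fix) == 0L) {
    return(structure(list(calls = empty_calls(),
                          annotations = empty_annotations()),
                     class = "nbs_vcf"))
  }
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  calls <- list(); anns <- list()
  for (i in seq_len(nrow(fix))) {
    contig <- normalize_contig(fix[i, "CHROM"])
    if (is.na(contig)) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    filt <- fix[i, "FILTER"]
    if (is.na(filt) || !nzchar(filt)) filt <- "."
    info <- fix[i, "INFO"]
    csq <- parse_csq_info(info)
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    ps_idx <- match("PS", fmt)
    for (ai in seq_along(alts)) {
      if (alts[ai] %in% c("*", ".") ) next
      v <- tryCatch(
        normalize_variant(contig, as.integer(fix[i, "POS"]), fix[i, "REF"],
                          alts[ai], ref_seq, ref_seq_offset),
        error = function(e) NULL)
      if (is.null(v)) next
      key <- variant_key(v$contig, v$pos, v$ref, v$alt)
      if (nrow(csq)) {
        a <- csq
        a$key <- key
        anns[[length(anns) + 1L]] <- a
      }
      for (s in samples) {
        cell <- strsplit(gt[i, s], ":", fixed = TRUE)[[1]]
        gt_s <- if (!is.na(gt_idx) && length(cell) >= gt_idx) cell[gt_idx] else NA
        if (is.na(gt_s) || gt_s %in% c(".", "./.", ".|.")) {
          if (is.na(gt_idx)) warning("record ", key, " sample ", s,
                                     ": missing GT, skipped")
          next
        }
        phased <- grepl("|", gt_s, fixed = TRUE)
        al <- suppressWarnings(as.integer(strsplit(gt_s, "[/|]")[[1]]))
        if (anyNA(al)) next
        n_alt <- sum(al == ai)
        if (n_alt == 0L) next
        zyg <- if (length(al) == 1L) "hemi"
               else if (n_alt == length(al)) "hom_alt" else "het"
        ps <- if (!is.na(ps_idx) && length(cell) >= ps_idx &&
                  nzchar(cell[ps_idx]) && cell[ps_idx] != ".")
          cell[ps_idx] else NA_character_
        hap <- if (phased && zyg == "het" && !is.na(ps))
          which(al == ai)[1] - 1L else NA_integer_
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = s, contig = v$contig, pos = v$pos, ref = v$ref,
          alt = v$alt, variant_class = v$variant_class, filter = filt,
          zygosity = zyg, phase_set = ps, haplotype_index = hap, key = key,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  anns <- if (length(anns)) unique(do.call(rbind, anns)) else empty_annotations()
  anns <- anns[, names(empty_annotations())]
  structure(list(calls = calls, annotations = anns), class = "nbs_vcf")
}

parse_csq_info <- function(info) {
  out <- empty_annotations()
  if (is.na(info) || !grepl("CSQ=", info, fixed = TRUE)) return(out)
  csq <- sub(".*CSQ=([^;]*).*", "\\1", info)
  blocks <- strsplit(csq, ",", fixed = TRUE)[[1]]
  rows <- lapply(blocks, function(b) {
    f <- strsplit(b, "|", fixed = TRUE)[[1]]
    length(f) <- length(CSQ_FIELDS)
    f[is.na(f)] <- ""
    data.frame(key = NA_character_, gene = f[1], transcript = f[2],
               consequence = f[3], impact = tolower(f[4]),
               protein_change = normalize_protein_change(f[5]),
               flags = f[6],
               cds_length = suppressWarnings(as.integer(f[7])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

format_csq_info <- function(ann) {
  if (is.null(ann) || nrow(ann) == 0L) return(".")
  blocks <- apply(ann, 1L, function(r) {
    paste(r[["gene"]], r[["transcript"]], r[["consequence"]], r[["impact"]],
          ifelse(is.na(r[["protein_change"]]), "", r[["protein_change"]]),
          ifelse(is.na(r[["flags"]]), "", r[["flags"]]),
          ifelse(is.na(r[["cds_length"]]), "", r[["cds_length"]]),
          sep = "|")
  })
  paste0("CSQ=", paste(blocks, collapse = ","))
}

#' Write genotype calls for one sample as a VCF
#'
#' Inverse of \code{\link{read_small_variant_vcf}} for a single sample:
#' annotations are embedded as a \code{CSQ} INFO field, phased genotypes are
#' written as \code{0|1}/\code{1|0} with a \code{PS} tag.
#'
#' @param calls Genotype-call data frame for one sample.
#' @param annotations Annotation data frame keyed by variant key (optional).
#' @param path Output file.
#' @param sample_id Sample column name; defaults to the one in \code{calls}.
#' @return \code{path}, invisibly.
#' @export
write_small_variant_vcf <- function(calls, annotations = NULL, path,
                                    sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(calls)) calls$sample_id[1] else "SAMPLE"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations: ", paste(CSQ_FIELDS, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    calls <- calls[order(ord_contig(calls$contig), calls$pos, calls$alt), ]
    for (i in seq_len(nrow(calls))) {
      r <- calls[i, ]
      ann <- if (!is.null(annotations) && nrow(annotations))
        annotations[annotations$key == r$key, , drop = FALSE] else NULL
      phased <- !is.na(r$haplotype_index)
      gt <- switch(r$zygosity,
                   het = if (phased) {
                     if (r$haplotype_index == 0L) "1|0" else "0|1"
                   } else "0/1",
                   hom_alt = "1/1",
                   hemi = "1")
      fmt <- "GT"; cell <- gt
      if (!is.na(r$phase_set)) {
        fmt <- "GT:PS"; cell <- paste0(gt, ":", r$phase_set)
      }
      body <- c(body, paste(r$contig, r$pos, ".", r$ref, r$alt, ".",
                            r$filter, format_csq_info(ann), fmt, cell,
                            sep = "\t"))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

ord_contig <- function(contig) match(contig, SUPPORTED_CONTIGS)

#' Read CNV/SV calls
#'
#' Accepts either a VCF with \code{SVTYPE} (\code{DEL}/\code{DUP}) and
#' \code{END} INFO keys, or a TSV with columns contig, start, end, type
#' (\code{loss}/\code{gain}), filter and optionally zygosity. Coordinates are
#' 1-based inclusive in both dialects.
#'
#' @param path Input file; dialect chosen by extension (\code{.vcf} vs TSV).
#' @param caller Label recorded in the \code{caller} column (e.g.
#'   \code{"cnv_caller"} or \code{"sv_caller"}).
#' @return Data frame: sample_id, contig, start, end, type, length, filter,
#'   zygosity, caller.
#' @export
read_cnv_calls <- function(path, caller = "cnv_caller") {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                    error = function(e) NULL)
    if (is.null(vcf) || nrow(vcf@fix) == 0L) return(empty_cnv(caller))
    fix <- vcf@fix
    info_get <- function(info, k) {
      m <- regmatches(info, regexec(paste0("(^|;)", k, "=([^;]+)"), info))[[1]]
      if (length(m) >= 3) m[3] else NA_character_
    }
    sample_id <- if (ncol(vcf@gt) >= 2) colnames(vcf@gt)[2] else NA_character_
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      svtype <- info_get(fix[i, "INFO"], "SVTYPE")
      end <- as.integer(info_get(fix[i, "INFO"], "END"))
      if (is.na(svtype) || is.na(end)) return(NULL)
      type <- c(DEL = "loss", DUP = "gain")[svtype]
      if (is.na(type)) return(NULL)
      zyg <- "het"
      if (ncol(vcf@gt) >= 2) {
        g <- strsplit(vcf@gt[i, 2], ":", fixed = TRUE)[[1]][1]
        if (g %in% c("1/1", "1|1", "1")) zyg <- "hom_alt"
      }
      data.frame(sample_id = sample_id,
                 contig = normalize_contig(fix[i, "CHROM"]),
                 start = as.integer(fix[i, "POS"]), end = end, type = type,
                 filter = fix[i, "FILTER"], zygosity = zyg,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    out$start <- as.integer(out$start); out$end <- as.integer(out$end)
    out$contig <- normalize_contig(out$contig)
    if (is.null(out$zygosity)) out$zygosity <- "het"
    if (is.null(out$sample_id)) out$sample_id <- NA_character_
  }
  if (is.null(out) || nrow(out) == 0L) return(empty_cnv(caller))
  out <- out[!is.na(out$contig), , drop = FALSE]
  out$length <- out$end - out$start + 1L
  out$caller <- caller
  out[, c("sample_id", "contig", "start", "end", "type", "length", "filter",
          "zygosity", "caller")]
}

empty_cnv <- function(caller = "cnv_caller") {
  data.frame(sample_id = character(), contig = character(), start = integer(),
             end = integer(), type = character(), length = integer(),
             filter = character(), zygosity = character(),
             caller = character(), stringsAsFactors = FALSE)
}

read_tsv <- function(path, required = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(x))
    if (length(miss)) stop(basename(path), ": missing columns ",
                           paste(miss, collapse = ", "))
  }
  x
}

#' Read the gene-condition panel
#'
#' Expected columns: gene, condition, moi (monoallelic/biallelic/x_linked),
#' lof_mechanism, inclusion_list_only (logicals), contig, gene_start,
#' gene_end, transcript, tx_start, tx_end.
#'
#' @param path TSV file.
#' @return Panel data frame with normalized contigs.
#' @export
read_panel <- function(path) {
  p <- read_tsv(path, c("gene", "condition", "moi", "lof_mechanism",
                        "inclusion_list_only", "contig", "gene_start",
                        "gene_end", "transcript", "tx_start", "tx_end"))
  p$contig <- normalize_contig(p$contig)
  p$lof_mechanism <- as.logical(p$lof_mechanism)
  p$inclusion_list_only <- as.logical(p$inclusion_list_only)
  stopifnot(all(p$moi %in% c("monoallelic", "biallelic", "x_linked")))
  p
}

#' Read exon models (gene, transcript, start, end, coding)
#' @param path TSV file; 1-based inclusive coordinates.
#' @return Data frame with a logical \code{coding} column.
#' @export
read_exons <- function(path) {
  e <- read_tsv(path, c("gene", "transcript", "start", "end", "coding"))
  e$coding <- as.logical(e$coding)
  e
}

#' Read a knowledge-base table of classification records
#'
#' Columns: source (clinvar_like/cva_like/curated_commercial/
#' internal_inclusion), contig, pos, ref, alt, gene, protein_change,
#' classification, evidence_ids. Classifications are canonicalized to
#' P/LP/VUS/LB/B; composite "Pathogenic/Likely pathogenic" labels count as P.
#'
#' @param path TSV file.
#' @return Data frame with canonical classification and key columns.
#' @export
read_knowledge <- function(path) {
  k <- read_tsv(path, c("source", "contig", "pos", "ref", "alt", "gene",
                        "protein_change", "classification", "evidence_ids"))
  k$contig <- normalize_contig(k$contig)
  k$classification <- canonicalize_classification(k$classification)
  k$protein_change <- normalize_protein_change(k$protein_change)
  k$key <- variant_key(k$contig, k$pos, k$ref, k$alt)
  bad <- k$source == "internal_inclusion" &
    (is.na(k$evidence_ids) | !nzchar(k$evidence_ids))
  if (any(bad)) {
    warning(sum(bad), " internal inclusion record(s) without PubMed evidence",
            " dropped")
    k <- k[!bad, , drop = FALSE]
  }
  k
}

#' Canonicalize classification labels
#'
#' Case-insensitive; composite "pathogenic/likely pathogenic" and
#' "benign/likely benign" labels collapse to P and B.
#' @param x Character vector of labels.
#' @return Factor-free character vector over P/LP/VUS/LB/B (NA if unknown).
#' @export
canonicalize_classification <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(y))
  out[y %in% c("p", "pathogenic", "pathogenic/likely pathogenic",
               "pathogenic/likely_pathogenic")] <- "P"
  out[y %in% c("lp", "likely pathogenic", "likely_pathogenic")] <- "LP"
  out[y %in% c("vus", "uncertain significance", "uncertain_significance",
               "uncertain")] <- "VUS"
  out[y %in% c("lb", "likely benign", "likely_benign")] <- "LB"
  out[y %in% c("b", "benign", "benign/likely benign",
               "benign/likely_benign")] <- "B"
  out
}

#' Read the exclusion list (contig, pos, ref, alt, reason)
#' @param path TSV file.
#' @return Data frame with a \code{key} column.
#' @export
read_exclusion <- function(path) {
  x <- read_tsv(path, c("contig", "pos", "ref", "alt", "reason"))
  x$contig <- normalize_contig(x$contig)
  x$key <- variant_key(x$contig, x$pos, x$ref, x$alt)
  x
}

#' Read allele-frequency references
#'
#' \code{read_internal_af}: TSV contig, pos, ref, alt, af (internal cohort
#' allele frequency, a fraction in [0,1]).
#' \code{read_population_af}: long TSV contig, pos, ref, alt, tier, af —
#' one row per population data set ("tier") in which the variant was seen.
#' Variants absent from a table are treated as frequency 0 (absent = rare).
#'
#' @param path TSV file.
#' @return Data frame with a \code{key} column.
#' @export
read_internal_af <- function(path) {
  x <- read_tsv(path, c("contig", "pos", "ref", "alt", "af"))
  x$contig <- normalize_contig(x$contig)
  x$af <- as.numeric(x$af)
  stopifnot(all(x$af >= 0 & x$af <= 1))
  x$key <- variant_key(x$contig, x$pos, x$ref, x$alt)
  x
}

#' @rdname read_internal_af
#' @export
read_population_af <- function(path) {
  x <- read_tsv(path, c("contig", "pos", "ref", "alt", "tier", "af"))
  x$contig <- normalize_contig(x$contig)
  x$af <- as.numeric(x$af)
  stopifnot(all(x$af >= 0 & x$af <= 1))
  x$key <- variant_key(x$contig, x$pos, x$ref, x$alt)
  x
}

#' Read the CNV reference frequency set
#' @param path TSV with contig, start, end, type (loss/gain), frequency.
#' @return Data frame.
#' @export
read_cnv_reference <- function(path) {
  x <- read_tsv(path, c("contig", "start", "end", "type", "frequency"))
  x$contig <- normalize_contig(x$contig)
  x$frequency <- as.numeric(x$frequency)
  stopifnot(all(x$frequency >= 0 & x$frequency <= 1))
  x
}

#' Read a companion-variant table
#'
#' Maps a trigger variant (one whose prioritization should prompt a manual
#' genotype check of related alleles, e.g. components of a complex allele) to
#' its companion variant keys.
#' @param path TSV with trigger_contig/pos/ref/alt, companion_contig/pos/ref/
#'   alt and a free-text label.
#' @return Data frame with \code{trigger_key} and \code{companion_key}.
#' @export
read_companion_table <- function(path) {
  x <- read_tsv(path, c("trigger_contig", "trigger_pos", "trigger_ref",
                        "trigger_alt", "companion_contig", "companion_pos",
                        "companion_ref", "companion_alt", "label"))
  x$trigger_key <- variant_key(normalize_contig(x$trigger_contig),
                               x$trigger_pos, x$trigger_ref, x$trigger_alt)
  x$companion_key <- variant_key(normalize_contig(x$companion_contig),
                                 x$companion_pos, x$companion_ref,
                                 x$companion_alt)
  x
}

#' Read a variant-pair co-occurrence table
#' @param path TSV with variant_a, variant_b (variant keys) and prediction
#'   (same_haplotype/different_haplotypes/uncertain).
#' @return Data frame.
#' @export
read_cooccurrence_table <- function(path) {
  x <- read_tsv(path, c("variant_a", "variant_b", "prediction"))
  stopifnot(all(x$prediction %in%
                  c("same_haplotype", "different_haplotypes", "uncertain")))
  x
}

#' Read BED intervals (0-based half-open on disk, 1-based inclusive returned)
#'
#' This is the package's single BED conversion point: columns beyond the
#' third are preserved as-is, \code{start} gains 1 and \code{end} is kept
#' (half-open end equals inclusive end after the start shift).
#'
#' @param path BED file (no header).
#' @param extra_names Names for columns 4+ if present.
#' @return Data frame contig, start, end (1-based inclusive), extras.
#' @export
read_bed <- function(path, extra_names = NULL) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("contig", "start", "end")
  if (ncol(x) > 3 && !is.null(extra_names)) {
    names(x)[4:(3 + length(extra_names))] <- extra_names
  }
  x$contig <- normalize_contig(x$contig)
  x$start <- as.integer(x$start) + 1L
  x$end <- as.integer(x$end)
  x
}

#' Read a bedGraph-style depth track
#'
#' Four columns (contig, start, end, depth), 0-based half-open on disk;
#' returned 1-based inclusive. The depth values are expected to come from a
#' coverage tool applied with the pipeline's read filters (MQ > 10, BQ > 30,
#' soft-clipped reads removed); those filters are provenance of the input,
#' not recomputed here.
#'
#' @param path bedGraph file (no header).
#' @return Data frame contig, start, end, depth.
#' @export
read_depth_track <- function(path) {
  x <- read_bed(path, extra_names = "depth")
  x$depth <- as.numeric(x$depth)
  x
}
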