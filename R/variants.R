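#' Normalize a variant to its minimal anchored representation
#'
#' Two variant records describe the same mutation when they hit the same
#' genomic locus with the same alternative allele. Raw VCF records (and
#' multi-allelic splits) often carry padding bases, so sameness is decided on
#' a trimmed representation: the shared trailing suffix of `ref` and `alt` is
#' removed first, then the shared leading prefix with `pos` advanced
#' accordingly, keeping one anchor base whenever either allele would otherwise
#' become empty (the usual VCF indel convention).
#'
#' The function is vectorized, deterministic and idempotent.
#'
#' @param chrom character vector of chromosome names (`"1"`..`"22"`, `"X"`, ...).
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference / alternate alleles
#'   (`A`/`C`/`G`/`T` strings, non-empty).
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt` and `id`
#'   (the canonical identifier from [variant_id()]).
#' @examples
#' normalize_variant("1", 100, "AT", "AG")   # -> 1:101 T>G
#' normalize_variant("12", 112036782, "G", "GGCTGCTGCTGCTGC")  # anchored insertion kept
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant position must be a positive 1-based integer", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad))
    stop("alleles must be non-empty A/C/G/T strings; offending ref/alt: ",
         paste(ref[bad], alt[bad], sep = "/", collapse = ", "), call. = FALSE)

  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # trailing suffix first
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # leading prefix, keeping one anchor base when an allele would empty
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  if (any(ref == alt))
    stop("ref and alt identical after trimming (not a variant): ",
         paste(chrom[ref == alt], pos[ref == alt], sep = ":", collapse = ", "),
         call. = FALSE)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             id = variant_id(chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

#' Canonical variant identifier
#'
#' Produces a string key on which VCF-style anchored records and ANNOVAR-style
#' dash-coded records agree. SNVs and balanced substitutions are keyed as
#' `chrom:pos:ref:alt`. Anchored insertions (`ref` a single base that prefixes
#' `alt`) are keyed at the anchor base with a `-` reference
#' (`chrom:pos:-:inserted`); anchored deletions are keyed at the first deleted
#' base with a `-` alternate (`chrom:pos+1:deleted:-`). This is exactly the
#' coordinate convention of ANNOVAR tables, so no reference genome is needed
#' to compare the two dialects.
#'
#' Alleles already written in dash form (`ref` or `alt` equal to `"-"`) are
#' keyed directly.
#'
#' @param chrom,pos,ref,alt vectors as in [normalize_variant()]; alleles may
#'   additionally be `"-"`.
#' @return character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  id <- character(n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (r == "-" || a == "-") {
      id[i] <- paste(chrom[i], p, r, a, sep = ":")
    } else if (nchar(r) == 1L && nchar(a) > 1L && substr(a, 1L, 1L) == r) {
      id[i] <- paste(chrom[i], p, "-", substr(a, 2L, nchar(a)), sep = ":")
    } else if (nchar(a) == 1L && nchar(r) > 1L && substr(r, 1L, 1L) == a) {
      id[i] <- paste(chrom[i], p + 1L, substr(r, 2L, nchar(r)), "-", sep = ":")
    } else {
      id[i] <- paste(chrom[i], p, r, a, sep = ":")
    }
  }
  id
}

#' Convert an ANNOVAR-style (Chr, Start, Ref, Alt) row to the canonical id
#'
#' ANNOVAR writes insertions as `Start = anchor base, Ref = "-"` and deletions
#' as `Start = first deleted base, Alt = "-"`; substitutions are plain.
#' Substitution alleles are trimmed through [normalize_variant()] so that the
#' id matches the one derived from VCF records.
#'
#' @param chrom,start,ref,alt vectors from an annotation table; `"-"` allowed.
#' @return character vector of canonical identifiers.
#' @keywords internal
annovar_id <- function(chrom, start, ref, alt) {
  n <- max(length(chrom), length(start), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  dash <- ref == "-" | alt == "-"
  bad <- !dash & (!grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt) | ref == alt)
  if (any(bad))
    stop("annotation row cannot be normalized at ",
         paste(chrom[bad], start[bad], sep = ":", collapse = ", "), call. = FALSE)
  out <- character(n)
  out[dash] <- variant_id(chrom[dash], start[dash], ref[dash], alt[dash])
  if (any(!dash)) {
    nv <- normalize_variant(chrom[!dash], start[!dash], ref[!dash], alt[!dash])
    out[!dash] <- nv$id
  }
  out
}
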