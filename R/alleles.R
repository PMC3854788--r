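#' Define a wild-type target region
#'
#' Anchors an amplicon to coding and protein coordinates: the first printed
#' base has coding position `cds_start_nt`, translation of the region begins
#' after `frame_offset` bases, and that first complete codon encodes residue
#' `first_residue` at protein position `first_residue_number`. Absolute
#' residue numbers in consequences derive from this anchor, so the full-gene
#' CDS is never needed.
#'
#' @param sequence wild-type nucleotide string (A/C/G/T).
#' @param cds_start_nt 1-based coding coordinate of the first base.
#' @param frame_offset bases to skip before the first complete codon (0-2).
#' @param first_residue_number protein position of that codon.
#' @param first_residue expected one-letter amino acid of that codon;
#'   checked against the translation.
#' @return a list of class `target_region`.
#' @examples
#' fx <- kif7_allele_fixtures()
#' fx$region
#' @export
target_region <- function(sequence, cds_start_nt, frame_offset = 0L,
                          first_residue_number = 1L, first_residue = NULL) {
  sequence <- toupper(sequence)
  check_nucleotides(sequence)
  if (!frame_offset %in% 0:2) stop("`frame_offset` must be 0, 1 or 2")
  region <- structure(list(sequence = sequence,
                           cds_start_nt = as.integer(cds_start_nt),
                           frame_offset = as.integer(frame_offset),
                           first_residue_number = as.integer(first_residue_number),
                           first_residue = first_residue),
                      class = "target_region")
  if (!is.null(first_residue)) {
    aa1 <- substr(translate_region(region, sequence), 1, 1)
    if (aa1 != first_residue)
      stop("frame anchor check failed: first codon translates to ", aa1,
           " not ", first_residue)
  }
  region
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> %d nt, cds %d-%d, frame offset %d, first residue %s%d\n",
              nchar(x$sequence), x$cds_start_nt,
              x$cds_start_nt + nchar(x$sequence) - 1L, x$frame_offset,
              if (is.null(x$first_residue)) "?" else x$first_residue,
              x$first_residue_number))
  invisible(x)
}

check_nucleotides <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0)
    stop("non-ACGT character '", substr(seq, bad, bad), "' at position ", bad)
  invisible(seq)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1] - 1L
}

#' Call a single contiguous indel against a target region
#'
#' Aligns a mutant amplicon to the wild-type region assuming a single
#' contiguous insertion or deletion — the situation produced by
#' nuclease-induced lesions at one cut site. The mutant sequence may extend
#' past the 3' end of the printed wild-type region (as when a sequencing
#' read continues into downstream sequence); the call then reconstructs the
#' mutant up to the region covered by the wild type. Placements that are
#' ambiguous in repeat context follow `policy`: `"leftmost"` (the 5'-most
#' placement, default) or `"rightmost"` (the HGVS 3' rule).
#'
#' @param wild_type a [target_region()].
#' @param mutant_sequence nucleotide string.
#' @param policy `"leftmost"` or `"rightmost"`.
#' @return a list of class `indel_call` with `kind` ("deletion" or
#'   "insertion"), `ref_allele` (deleted or inserted bases), `position_nt`
#'   (coding coordinate of the first affected base), `region_pos` (1-based
#'   position within the printed region), `length_nt`, `alignment_policy`.
#' @export
call_indel <- function(wild_type, mutant_sequence,
                       policy = c("leftmost", "rightmost")) {
  policy <- match.arg(policy)
  if (!inherits(wild_type, "target_region")) stop("expected a `target_region`")
  wt <- wild_type$sequence
  mut <- toupper(mutant_sequence)
  check_nucleotides(mut)
  if (wt == mut) stop("no variant: sequences are identical")
  k <- common_prefix_len(wt, mut)
  # candidate single edits at the first mismatch: a deletion of d wild-type
  # bases or an insertion of i mutant bases, after which the rest of the
  # wild type must be reproduced in full (the mutant may extend past the
  # region's 3' end, e.g. a read running into downstream sequence). The
  # minimal-length edit across both kinds is taken (parsimony).
  mut_rest <- substr(mut, k + 1L, nchar(mut))
  wt_rest <- substr(wt, k + 1L, nchar(wt))
  # an edit that reconstructs the mutant exactly (no 3' tail) takes
  # precedence over a shorter edit plus assumed downstream tail
  if (nchar(wt) > nchar(mut)) {
    d <- nchar(wt) - nchar(mut)
    if (identical(mut_rest, substr(wt, k + d + 1L, nchar(wt))))
      return(finish_indel_call(wild_type,
        list(kind = "deletion", len = d, pos = k + 1L,
             allele = substr(wt, k + 1L, k + d)), policy))
  } else if (nchar(mut) > nchar(wt)) {
    i <- nchar(mut) - nchar(wt)
    if (identical(substr(mut, k + i + 1L, nchar(mut)), wt_rest))
      return(finish_indel_call(wild_type,
        list(kind = "insertion", len = i, pos = k + 1L,
             allele = substr(mut, k + 1L, k + i)), policy))
  }
  d_del <- NA_integer_
  for (d in seq_len(max(0L, nchar(wt) - k))) {
    wt_after <- substr(wt, k + d + 1L, nchar(wt))
    # a call that assumes a mutant 3' tail must re-anchor on enough
    # wild-type sequence after the gap to be credible (8 nt), and a
    # deletion running to the region's end leaves no anchor at all
    anchor_ok <- if (nchar(mut_rest) > nchar(wt_after))
      nchar(wt_after) >= 8L else nzchar(wt_after) || !nzchar(mut_rest)
    if (anchor_ok && startsWith(mut_rest, wt_after)) {
      d_del <- d
      break
    }
  }
  d_ins <- NA_integer_
  for (i in seq_len(max(0L, nchar(mut) - k))) {
    if (startsWith(substr(mut, k + i + 1L, nchar(mut)), wt_rest) &&
        (nzchar(wt_rest) || k + i == nchar(mut))) {
      d_ins <- i
      break
    }
  }
  call <- if (!is.na(d_del) && (is.na(d_ins) || d_del <= d_ins))
    list(kind = "deletion", len = d_del, pos = k + 1L,
         allele = substr(wt, k + 1L, k + d_del))
  else if (!is.na(d_ins))
    list(kind = "insertion", len = d_ins, pos = k + 1L,
         allele = substr(mut, k + 1L, k + d_ins))
  else NULL
  if (is.null(call)) {
    # locate the two mismatching loci for the error message
    rk <- common_prefix_len(paste(rev(strsplit(wt, "")[[1]]), collapse = ""),
                            paste(rev(strsplit(mut, "")[[1]]), collapse = ""))
    stop("complex allele: differences are not a single contiguous indel ",
         "(first mismatch at region position ", k + 1L,
         ", last at position ", nchar(wt) - rk, ")")
  }
  finish_indel_call(wild_type, call, policy)
}

# normalize an indel placement within its repeat run per policy and build
# the indel_call object; the prefix scan that found it gives the 3'-most
# placement
finish_indel_call <- function(wild_type, call, policy) {
  wt <- wild_type$sequence
  if (policy == "leftmost") {
    wtv <- strsplit(wt, "")[[1]]
    if (call$kind == "deletion") {
      while (call$pos > 1L && wtv[call$pos - 1L] == wtv[call$pos + call$len - 1L])
        call$pos <- call$pos - 1L
      call$allele <- substr(wt, call$pos, call$pos + call$len - 1L)
    } else {
      iv <- strsplit(call$allele, "")[[1]]
      while (call$pos > 1L && wtv[call$pos - 1L] == iv[call$len]) {
        iv <- c(iv[call$len], iv[-call$len])
        call$pos <- call$pos - 1L
      }
      call$allele <- paste(iv, collapse = "")
    }
  }
  if (policy == "rightmost") {
    wtv <- strsplit(wt, "")[[1]]
    if (call$kind == "deletion") {
      while (call$pos + call$len <= nchar(wt) &&
             wtv[call$pos] == wtv[call$pos + call$len])
        call$pos <- call$pos + 1L
      call$allele <- substr(wt, call$pos, call$pos + call$len - 1L)
    } else {
      iv <- strsplit(call$allele, "")[[1]]
      while (call$pos <= nchar(wt) && wtv[call$pos] == iv[1]) {
        iv <- c(iv[-1], iv[1])
        call$pos <- call$pos + 1L
      }
      call$allele <- paste(iv, collapse = "")
    }
  }
  structure(list(kind = call$kind,
                 ref_allele = call$allele,
                 position_nt = wild_type$cds_start_nt + call$pos - 1L,
                 region_pos = call$pos,
                 length_nt = call$len,
                 alignment_policy = policy),
            class = "indel_call")
}

#' @export
print.indel_call <- function(x, ...) {
  cat(sprintf("<indel_call> %d-bp %s of %s at cds nt %d (%s placement)\n",
              x$length_nt, x$kind, x$ref_allele, x$position_nt,
              x$alignment_policy))
  invisible(x)
}

#' Apply an indel call to the wild-type region
#'
#' Reconstructs the mutant sequence implied by a call; used to verify the
#' round trip `apply_indel(call_indel(wt, mut)) == mut`.
#'
#' @param wild_type a [target_region()].
#' @param call an `indel_call`.
#' @return the rearranged nucleotide string.
#' @export
apply_indel <- function(wild_type, call) {
  wt <- wild_type$sequence
  p <- call$region_pos
  if (call$kind == "deletion")
    paste0(substr(wt, 1, p - 1L), substr(wt, p + call$length_nt, nchar(wt)))
  else
    paste0(substr(wt, 1, p - 1L), call$ref_allele,
           substr(wt, p, nchar(wt)))
}

#' Translate a sequence in the frame of a target region
#'
#' Standard-code translation of the complete codons of `sequence`, starting
#' after the region's `frame_offset`; a trailing partial codon is dropped.
#' Translation runs up to and including the first stop codon (rendered
#' `*`).
#'
#' @param region a [target_region()] supplying the frame.
#' @param sequence nucleotide string (defaults to the region's own).
#' @return an amino-acid string.
#' @examples
#' fx <- kif7_allele_fixtures()
#' translate_region(fx$region)  # "SKFHFVDLAGSE"
#' @export
translate_region <- function(region, sequence = region$sequence) {
  if (!inherits(region, "target_region")) stop("expected a `target_region`")
  sequence <- toupper(sequence)
  check_nucleotides(sequence)
  body <- substr(sequence, region$frame_offset + 1L, nchar(sequence))
  n_codon <- nchar(body) %/% 3L
  if (n_codon == 0L) stop("sequence too short to translate in this frame")
  body <- substr(body, 1L, 3L * n_codon)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(body)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) aa <- substr(aa, 1L, stop_at)
  aa
}

#' Protein consequence of an indel
#'
#' Derives the encoded protein change of a validated single-indel call in
#' the notation used for engineered alleles:
#' \itemize{
#'   \item indel length not divisible by 3: frameshift. Wild-type and
#'     mutant translations are compared residue by residue; the first
#'     differing residue `r` names the change and the new reading frame's
#'     first stop gives `fsX<k>`, counting `r` itself as 1 (e.g.
#'     `D250RfsX7`). If no stop occurs within the sequenced region the
#'     stop offset is reported as beyond the region rather than invented.
#'   \item indel length divisible by 3: in-frame deletion, resolved at the
#'     protein level by longest common flanks, so deletions straddling
#'     codon boundaries are named correctly (e.g. `D250del`).
#' }
#'
#' @param region a [target_region()].
#' @param indel an `indel_call` from [call_indel()].
#' @param mutant_sequence the mutant nucleotide string.
#' @return a list of class `protein_consequence` with `kind`, `notation`,
#'   `first_affected_residue`, `fs_stop_offset` (`NA` when the stop lies
#'   beyond the region), `stop_beyond_region`, `mutant_peptide` (from the
#'   first altered residue to the stop).
#' @export
protein_consequence <- function(region, indel, mutant_sequence) {
  if (!inherits(indel, "indel_call")) stop("expected an `indel_call`")
  wt_prot <- translate_region(region)
  mut_prot <- translate_region(region, mutant_sequence)
  wtv <- strsplit(wt_prot, "")[[1]]
  mtv <- strsplit(mut_prot, "")[[1]]
  base <- region$first_residue_number
  if (indel$length_nt %% 3L != 0L) {
    n <- min(length(wtv), length(mtv))
    diffs <- which(wtv[seq_len(n)] != mtv[seq_len(n)])
    r <- if (length(diffs)) diffs[1] else n + 1L
    if (r > length(mtv))
      stop("mutant translation does not extend to the frameshift")
    abs_r <- base + r - 1L
    stop_idx <- which(mtv == "*")
    stop_idx <- stop_idx[stop_idx >= r]
    beyond <- length(stop_idx) == 0L
    k <- if (beyond) NA_integer_ else stop_idx[1] - r + 1L
    ref_aa <- if (r <= length(wtv)) wtv[r] else "?"
    notation <- paste0(ref_aa, abs_r, mtv[r], "fsX", if (beyond) "?" else k)
    peptide <- paste(mtv[r:length(mtv)], collapse = "")
    structure(list(kind = "frameshift", notation = notation,
                   first_affected_residue = abs_r, fs_stop_offset = k,
                   stop_beyond_region = beyond, mutant_peptide = peptide),
              class = "protein_consequence")
  } else {
    # in-frame: longest common flanks at protein level
    pp <- 0L
    while (pp < min(length(wtv), length(mtv)) && wtv[pp + 1L] == mtv[pp + 1L])
      pp <- pp + 1L
    ss <- 0L
    while (ss < min(length(wtv), length(mtv)) - pp &&
           wtv[length(wtv) - ss] == mtv[length(mtv) - ss])
      ss <- ss + 1L
    del_from <- pp + 1L
    del_to <- length(wtv) - ss
    if (del_to < del_from) {
      return(structure(list(kind = "synonymous", notation = "=",
                            first_affected_residue = NA_integer_,
                            fs_stop_offset = NA_integer_,
                            stop_beyond_region = FALSE,
                            mutant_peptide = ""),
                       class = "protein_consequence"))
    }
    n_del <- del_to - del_from + 1L
    if (length(mtv) + n_del != length(wtv)) {
      # same-length replacement run: missense / delins at protein level
      notation <- paste0(wtv[del_from], base + del_from - 1L,
                         mtv[del_from])
      return(structure(list(kind = "missense", notation = notation,
                            first_affected_residue = base + del_from - 1L,
                            fs_stop_offset = NA_integer_,
                            stop_beyond_region = FALSE,
                            mutant_peptide = mtv[del_from]),
                       class = "protein_consequence"))
    }
    abs_from <- base + del_from - 1L
    abs_to <- base + del_to - 1L
    notation <- if (n_del == 1L)
      paste0(wtv[del_from], abs_from, "del")
    else
      paste0(wtv[del_from], abs_from, "_", wtv[del_to], abs_to, "del")
    structure(list(kind = "inframe_deletion", notation = notation,
                   first_affected_residue = abs_from,
                   fs_stop_offset = NA_integer_, stop_beyond_region = FALSE,
                   mutant_peptide = ""),
              class = "protein_consequence")
  }
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s (%s)\n", x$notation, x$kind))
  invisible(x)
}

#' Packaged zebrafish kif7 allele fixtures
#'
#' The wild-type ZFN target region of zebrafish *kif7* (coding nucleotides
#' 729-765, third coding exon) and the three recovered deletion alleles
#' (i271, i272, i273), read from the package's FASTA fixture, together with
#' the frame anchor: translation starts one base into the printed region and
#' the first complete codon encodes serine 244.
#'
#' @return a list with `sequences` (named character vector: `wild-type`,
#'   `i271`, `i272`, `i273`) and `region` (a [target_region()] for the
#'   wild type).
#' @export
kif7_allele_fixtures <- function() {
  path <- system.file("extdata", "kif7_alleles.fasta", package = "punctaseg",
                      mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(path)
  sequences <- stats::setNames(as.character(seqs), names(seqs))
  list(sequences = sequences,
       region = target_region(sequences[["wild-type"]],
                              cds_start_nt = 729L, frame_offset = 1L,
                              first_residue_number = 244L,
                              first_residue = "S"))
}
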