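#' BLOSUM62 substitution matrix
#'
#' Standard 20 x 20 half-bit BLOSUM62 scores over the one-letter amino-acid
#' alphabet, inlined as plain source (cross-checked against the canonical
#' distribution).
#' @return integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  m <- matrix(c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4),
    nrow = 20L, byrow = TRUE, dimnames = list(aa, aa))
  m
}

#' Pseudo-groove BLOSUM62 similarity to a reference allele
#'
#' For each allele's pre-aligned, gapless pseudo-groove sequence, the raw
#' score is the position-wise BLOSUM62 sum against the reference sequence;
#' the normalized identity divides by the reference self-score, so the
#' reference scores exactly 1.
#'
#' @param pseudo_sequences named character vector (allele -> fixed-length
#'   pseudo-sequence).
#' @param reference reference allele name (must be present).
#' @return data.frame (`allele`, `raw`, `normalized`) in input order.
#' @export
groove_similarity <- function(pseudo_sequences, reference) {
  if (!reference %in% names(pseudo_sequences))
    stop("reference allele not in the pseudo-sequence set: ", reference)
  b62 <- blosum62()
  ref_seq <- strsplit(pseudo_sequences[[reference]], "")[[1L]]
  lens <- nchar(pseudo_sequences)
  if (length(unique(lens)) != 1L)
    stop("pseudo-sequences must share one length (got ",
         paste(unique(lens), collapse = ", "), ")")
  bad_ref <- setdiff(ref_seq, rownames(b62))
  if (length(bad_ref) > 0L)
    stop("non-standard residue letter(s): ", paste(bad_ref, collapse = ""))
  self_score <- sum(b62[cbind(ref_seq, ref_seq)])
  raw <- vapply(pseudo_sequences, function(s) {
    q <- strsplit(s, "")[[1L]]
    bl <- setdiff(q, rownames(b62))
    if (length(bl) > 0L)
      stop("non-standard residue letter(s): ", paste(bl, collapse = ""))
    sum(b62[cbind(q, ref_seq)])
  }, numeric(1))
  data.frame(allele = names(pseudo_sequences), raw = as.numeric(raw),
             normalized = as.numeric(raw) / self_score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a predictor pseudo-sequence file
#'
#' Whitespace-delimited `allele pseudo_sequence` lines (the positionally
#' aligned groove-lining positions used by binding predictors).
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_pseudo_sequences <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("allele", "pseudo"))
  stats::setNames(tab$pseudo, tab$allele)
}

#' Classify binders from percentile ranks
#'
#' `strong` iff rank <= `strong_thr`; `weak` iff `strong_thr` < rank <=
#' `weak_thr`; `non` otherwise (the predictor's default 0.5/2.0 thresholds).
#' The classes partition the records.
#'
#' @param records data.frame with a `percent_rank_BA` column (>= 0).
#' @param strong_thr,weak_thr percentile-rank thresholds.
#' @return records with an added `binder_class` factor.
#' @export
classify_binders <- function(records, strong_thr = 0.5, weak_thr = 2.0) {
  r <- records$percent_rank_BA
  if (is.null(r)) stop("records must carry percent_rank_BA")
  if (any(r < 0)) stop("negative percentile rank")
  cls <- ifelse(r <= strong_thr, "strong",
                ifelse(r <= weak_thr, "weak", "non"))
  records$binder_class <- factor(cls, levels = c("strong", "weak", "non"))
  records
}

#' Read a netMHCpan-style tabular prediction output
#'
#' Whitespace-delimited with a header naming at least `allele` (or `MHC`),
#' `peptide`, and a BA percentile-rank column (`%Rank_BA`, `rank_BA` or
#' `percent_rank_BA`); an affinity column (`Aff(nM)`, `affinity_nM`) is
#' carried through when present.
#'
#' @param path file path.
#' @return data.frame (`allele`, `peptide`, `percent_rank_BA`,
#'   `affinity_nM`).
#' @export
read_binder_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  pick <- function(opts) {
    hit <- intersect(opts, names(tab))
    if (length(hit) == 0L) return(NULL)
    tab[[hit[1L]]]
  }
  allele <- pick(c("allele", "Allele", "MHC"))
  peptide <- pick(c("peptide", "Peptide"))
  rank <- pick(c("percent_rank_BA", "%Rank_BA", "rank_BA", "BA_Rank"))
  if (is.null(allele) || is.null(rank))
    stop("binder table must name an allele and a BA percentile-rank column")
  aff <- pick(c("affinity_nM", "Aff(nM)", "Aff_nM"))
  data.frame(allele = allele,
             peptide = if (is.null(peptide)) NA_character_ else peptide,
             percent_rank_BA = as.numeric(rank),
             affinity_nM = if (is.null(aff)) NA_real_ else as.numeric(aff),
             stringsAsFactors = FALSE)
}

#' Kullback-Leibler sequence logo matrix
#'
#' Per position, information `I = sum_a p_a log2(p_a / q_a)` (0*log0 = 0)
#' against a strictly positive background `q`; letter heights are
#' `p_a * I` (proportional to `p_a` within the column), positive letters
#' only. Information is non-negative whenever `p` and `q` are distributions
#' (Gibbs' inequality).
#'
#' @param peptides character vector of equal-length peptides, or a
#'   positions x 20 probability matrix (columns named by amino acid).
#' @param background named numeric background distribution over the
#'   20-letter alphabet (default uniform). Must be strictly positive and
#'   sum to 1.
#' @param pseudocount added per amino acid before normalizing observed
#'   counts (default 0).
#' @return object of class `MotifMatrix`: list with `p` (positions x 20),
#'   `q`, `information` (bits per position) and `heights` (positions x 20).
#' @export
kl_logo <- function(peptides, background = NULL, pseudocount = 0) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20L), aa)
  if (!all(aa %in% names(background)))
    stop("background must cover the 20-letter alphabet")
  q <- background[aa]
  if (any(q <= 0) || abs(sum(q) - 1) > 1e-8)
    stop("background must be strictly positive and sum to 1")
  if (is.matrix(peptides)) {
    p <- peptides[, aa, drop = FALSE]
    if (any(abs(rowSums(p) - 1) > 1e-8))
      stop("probability rows must sum to 1")
  } else {
    lens <- nchar(peptides)
    if (length(unique(lens)) != 1L)
      stop("peptides must share one length")
    l <- lens[1L]
    p <- matrix(0, l, 20L, dimnames = list(NULL, aa))
    for (pos in seq_len(l)) {
      letters_at <- substr(peptides, pos, pos)
      bad <- setdiff(unique(letters_at), aa)
      if (length(bad) > 0L)
        stop("non-standard residue letter(s): ", paste(bad, collapse = ""))
      counts <- table(factor(letters_at, levels = aa)) + pseudocount
      p[pos, ] <- counts / sum(counts)
    }
  }
  info <- apply(p, 1L, function(pr) {
    nz <- pr > 0
    sum(pr[nz] * log2(pr[nz] / q[nz]))
  })
  heights <- p * info
  structure(list(p = p, q = q, information = as.numeric(info),
                 heights = heights),
            class = "MotifMatrix")
}

normalize_allele <- function(x) {
  toupper(gsub("[[:space:]]", "", gsub("[*]", "", x)))
}

#' Join binder records with population allele frequencies
#'
#' Left join on normalized allele names (case, `*` separators and
#' whitespace removed), then stable sort descending by global frequency
#' with missing frequencies last. Idempotent; duplicate allele rows in the
#' frequency table are an error.
#'
#' @param binders data.frame with an `allele` column.
#' @param freq_table data.frame with `allele` and `frequency` (percent)
#'   columns.
#' @return binders with `global_frequency` added, sorted.
#' @export
join_frequencies <- function(binders, freq_table) {
  if (!is.null(binders$global_frequency)) {
    binders$global_frequency <- NULL  # idempotent re-join
  }
  key_f <- normalize_allele(freq_table$allele)
  dup <- unique(freq_table$allele[duplicated(key_f)])
  if (length(dup) > 0L)
    stop("duplicate allele rows in the frequency table: ",
         paste(dup, collapse = ", "))
  key_b <- normalize_allele(binders$allele)
  binders$global_frequency <- freq_table$frequency[match(key_b, key_f)]
  ord <- order(-replace(binders$global_frequency,
                        is.na(binders$global_frequency), -Inf))
  out <- binders[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
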