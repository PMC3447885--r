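# Variable-gap consensus scanner for the CXC domain superfamily.
#
# The CXC superfamily consensus is a chain of ligand tokens (invariant Cys,
# with His admitted at ligand 2) separated by bounded variable gaps, closed
# by the signature Asn two positions after the ninth ligand:
#   C X [C/H] X2-13 C X4-7 C X C X5-60 C X2-4 C X1-2 C X2-15 C X N
# Pattern text uses "X" for exactly one arbitrary residue, "Xa-b" (or the
# typeset form "X_a-b_") for a gap of a..b arbitrary residues, and
# "[A/B]" for alternatives at one position.

CXC_CONSENSUS_TEXT <- "CX[C/H]X2-13CX4-7CXCX5-60CX2-4CX1-2CX2-15CXN"

#' Parse a variable-gap motif pattern
#'
#' @param text Pattern string; grammar: residue letters, bracketed
#'   alternatives `[C/H]`, `X` (exactly one arbitrary residue), `Xa-b` or
#'   `X_a-b_` (a..b arbitrary residues).  Adjacent gaps merge.
#' @param signature `"auto"` treats a terminal single-residue non-Cys
#'   token (the invariant Asn) as the signature rather than a ligand;
#'   `TRUE`/`FALSE` force the choice.
#' @return A `motif_pattern`: list of tokens, each either
#'   `list(type = "residue", allowed = <letters>)` or
#'   `list(type = "gap", min =, max =)`.
#' @examples
#' cxc_consensus()
#' parse_pattern("CXC")
#' @export
parse_pattern <- function(text, signature = "auto") {
  stopifnot(is.character(text), length(text) == 1L)
  # normalize typeset dashes and gap underscores
  raw <- gsub("–|—", "-", text)
  tokens <- list()
  push_gap <- function(a, b, at) {
    if (a > b) stop_input("malformed gap bounds %d-%d at offset %d", a, b, at)
    n <- length(tokens)
    if (n && tokens[[n]]$type == "gap") {
      tokens[[n]]$min <<- tokens[[n]]$min + a
      tokens[[n]]$max <<- tokens[[n]]$max + b
    } else {
      tokens[[length(tokens) + 1L]] <<- list(type = "gap", min = a, max = b)
    }
  }
  i <- 1L
  n <- nchar(raw)
  while (i <= n) {
    ch <- substr(raw, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(raw, i, n), fixed = TRUE)
      if (close < 0) stop_input("unclosed '[' at offset %d", i)
      body <- substr(raw, i + 1L, i + close - 2L)
      allowed <- toupper(strsplit(body, "/", fixed = TRUE)[[1]])
      if (!all(grepl("^[A-Z]$", allowed))) {
        stop_input("malformed alternative '[%s]' at offset %d", body, i)
      }
      tokens[[length(tokens) + 1L]] <- list(type = "residue", allowed = allowed)
      i <- i + close
    } else if (toupper(ch) == "X") {
      rest <- substr(raw, i + 1L, n)
      m <- regmatches(rest, regexec("^_?([0-9]+)-([0-9]+)_?", rest))[[1]]
      if (length(m)) {
        push_gap(as.integer(m[2]), as.integer(m[3]), i)
        i <- i + 1L + nchar(m[1])
      } else {
        push_gap(1L, 1L, i)
        i <- i + 1L
      }
    } else if (grepl("^[A-Za-z]$", ch)) {
      tokens[[length(tokens) + 1L]] <- list(type = "residue",
                                            allowed = toupper(ch))
      i <- i + 1L
    } else {
      stop_input("unknown symbol '%s' at offset %d", ch, i)
    }
  }
  res_idx <- which(vapply(tokens, `[[`, "", "type") == "residue")
  if (length(res_idx) < 2L) stop_input("pattern needs at least two residue tokens")
  if (res_idx[1] != 1L || res_idx[length(res_idx)] != length(tokens)) {
    stop_input("pattern must start and end with residue tokens")
  }
  has_sig <- if (identical(signature, "auto")) {
    last <- tokens[[length(tokens)]]
    length(res_idx) >= 3L && length(last$allowed) == 1L &&
      !"C" %in% last$allowed
  } else isTRUE(signature)
  structure(list(tokens = tokens, text = text, has_signature = has_sig),
            class = "motif_pattern")
}

#' @rdname parse_pattern
#' @export
cxc_consensus <- function() parse_pattern(CXC_CONSENSUS_TEXT)

#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(x$tokens, function(tk) {
    if (tk$type == "residue") {
      if (length(tk$allowed) > 1L) {
        paste0("[", paste(tk$allowed, collapse = "/"), "]")
      } else tk$allowed
    } else if (tk$min == 1L && tk$max == 1L) "X" else {
      sprintf("X%d-%d", tk$min, tk$max)
    }
  }, ""), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  nres <- sum(vapply(x$tokens, `[[`, "", "type") == "residue")
  cat(sprintf("<motif_pattern %s (%d residue tokens%s)>\n", format(x), nres,
              if (x$has_signature) ", terminal signature" else ""))
  invisible(x)
}

#' Inter-ligand gap bounds of a pattern
#'
#' @param pattern A [parse_pattern()] result.
#' @return Integer matrix with columns `min`, `max`, one row per gap token.
#' @export
pattern_gap_bounds <- function(pattern) {
  gaps <- Filter(function(tk) tk$type == "gap", pattern$tokens)
  cbind(min = vapply(gaps, `[[`, 0L, "min"),
        max = vapply(gaps, `[[`, 0L, "max"))
}

# all residue-token position tuples matching `tokens` with token k placed
# from sequence position pos onward
match_tokens <- function(chars, tokens, k, pos) {
  n <- length(chars)
  if (k > length(tokens)) return(list(integer(0)))
  tk <- tokens[[k]]
  if (tk$type == "residue") {
    if (pos > n || !chars[pos] %in% tk$allowed) return(list())
    lapply(match_tokens(chars, tokens, k + 1L, pos + 1L),
           function(rest) c(pos, rest))
  } else {
    out <- list()
    for (len in tk$min:tk$max) {
      if (pos + len > n) break
      out <- c(out, match_tokens(chars, tokens, k + 1L, pos + len))
    }
    out
  }
}

#' Scan a sequence for consensus matches
#'
#' Enumerates *all* distinct ligand-position tuples satisfying the pattern
#' (bounded backtracking over gap lengths), deduplicated by ligand tuple.
#' Output order is deterministic: by start position, then lexicographic in
#' the position tuple.  Overlapping matches are allowed.
#'
#' @param sequence Amino-acid string (case-insensitive) or a single-element
#'   named character vector; non-canonical letters never match residue
#'   tokens but are accepted inside gaps.
#' @param pattern A [parse_pattern()] result (default: the CXC superfamily
#'   consensus).
#' @param seq_id Sequence identifier carried into the matches.
#' @return List of `motif_match` objects, each with `seq_id`, `ligands`
#'   (residue-token positions excluding the signature), `signature_pos`
#'   (`NA` when the pattern has none), `gaps`, `span`.
#' @export
scan_motif <- function(sequence, pattern = cxc_consensus(),
                       seq_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(sequence))) names(sequence) else "seq"
  }
  chars <- strsplit(toupper(unname(sequence)), "")[[1]]
  tuples <- list()
  for (start in seq_along(chars)) {
    tuples <- c(tuples, match_tokens(chars, pattern$tokens, 1L, start))
  }
  if (length(tuples) == 0L) return(list())
  # deterministic order: by start, then lexicographic tuple
  keys <- vapply(tuples, function(tp) {
    paste(formatC(tp, width = 6, flag = "0"), collapse = ",")
  }, "")
  tuples <- tuples[order(keys)]
  matches <- lapply(tuples, function(tp) {
    ligands <- if (pattern$has_signature) tp[-length(tp)] else tp
    structure(list(
      seq_id = seq_id,
      ligands = ligands,
      signature_pos = if (pattern$has_signature) tp[length(tp)] else NA_integer_,
      gaps = diff(tp) - 1L,
      span = c(tp[1], tp[length(tp)])),
      class = "motif_match")
  })
  # dedup by ligand tuple, keeping the first occurrence
  lig_keys <- vapply(matches, function(m) paste(m$ligands, collapse = ","), "")
  matches[!duplicated(lig_keys)]
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("<motif_match %s: ligands %s%s>\n", x$seq_id,
              paste(x$ligands, collapse = ","),
              if (!is.na(x$signature_pos)) {
                sprintf("; signature at %d", x$signature_pos)
              } else ""))
  invisible(x)
}

#' Inter-ligand gap lengths of a match
#'
#' `gap_k = pos(ligand k+1) - pos(ligand k) - 1`; when the pattern carries
#' a terminal signature, the final entry is the ligand-to-signature gap.
#'
#' @param m A `motif_match`.
#' @return Named integer vector of gap lengths.
#' @export
gap_report <- function(m) {
  stopifnot(inherits(m, "motif_match"))
  pos <- c(m$ligands, if (!is.na(m$signature_pos)) m$signature_pos)
  gaps <- diff(pos) - 1L
  k <- length(m$ligands)
  names(gaps) <- c(paste0("g", seq_len(k - 1L)),
                   if (!is.na(m$signature_pos)) "ligand_to_signature")
  gaps
}

#' Find tandem (two-domain) motif arrangements
#'
#' Pairs of non-overlapping matches separated by at most `max_spacer`
#' residues.  EZ-type pre-SET tandems are immediately adjacent
#' (spacer 0); tesmin/TSO1-type tandems are separated by 40-60 residues.
#'
#' @param sequence Amino-acid string.
#' @param pattern A [parse_pattern()] result.
#' @param max_spacer Maximum residues between the first match's end and the
#'   second match's start.
#' @return Tibble with columns `first`, `second` (list-columns of
#'   `motif_match`) and `spacer`.
#' @export
tandem_scan <- function(sequence, pattern = cxc_consensus(), max_spacer = 0L) {
  if (max_spacer < 0L) stop_input("max_spacer must be >= 0")
  matches <- scan_motif(sequence, pattern)
  out <- list()
  for (i in seq_along(matches)) {
    for (j in seq_along(matches)) {
      if (i == j) next
      spacer <- matches[[j]]$span[1] - matches[[i]]$span[2] - 1L
      if (spacer >= 0L && spacer <= max_spacer) {
        out[[length(out) + 1L]] <- tibble::tibble(
          first = list(matches[[i]]), second = list(matches[[j]]),
          spacer = spacer)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(first = list(), second = list(),
                          spacer = integer()))
  }
  dplyr::bind_rows(out)
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Scan FASTA records and tabulate matches
#'
#' @param sequences Named character vector (e.g. from
#'   [read_fasta_sequences()]).
#' @param pattern A [parse_pattern()] result.
#' @return Tibble with one row per match: `seq_id`, `ligands`
#'   (comma-separated), `signature_pos`, `start`, `end`.
#' @export
scan_fasta <- function(sequences, pattern = cxc_consensus()) {
  rows <- list()
  for (id in names(sequences)) {
    for (m in scan_motif(sequences[[id]], pattern, seq_id = id)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = id,
        ligands = paste(m$ligands, collapse = ","),
        signature_pos = m$signature_pos,
        start = m$span[1], end = m$span[2])
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(seq_id = character(), ligands = character(),
                          signature_pos = integer(), start = integer(),
                          end = integer()))
  }
  dplyr::bind_rows(rows)
}
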