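## ---------------------------------------------------------------------------
## Alignments are named character vectors of equal-length nucleotide strings.
## For likelihood/parsimony work each site is encoded as a 4-bit state set
## (A=1, C=2, G=4, T=8); IUPAC ambiguity codes map to the union of their
## states and '-'/'?'/'N' to the full set (missing data).
## ---------------------------------------------------------------------------

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L,
                N = 15L, "-" = 15L, "?" = 15L, "." = 15L, X = 15L)

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences, all equal length.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- sub("\\s.*$", "", names)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    toupper(gsub("\\s", "", paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")))
  }, character(1))
  names(seqs) <- names
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths; alignment required")
  if (anyDuplicated(names)) stop("duplicate sequence names in ", path)
  seqs
}

#' Write a FASTA alignment
#' @param aln named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(aln)) {
    writeLines(paste0(">", nm), con)
    s <- aln[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## Encode sequences (for taxa in the given order) as an ntaxa x nsites
## integer matrix of 4-bit state sets.
encode_alignment <- function(aln, taxa) {
  miss <- setdiff(taxa, names(aln))
  if (length(miss))
    stop("no sequence for taxa: ", paste(miss, collapse = ", "))
  S <- nchar(aln[[taxa[1L]]])
  m <- matrix(0L, nrow = length(taxa), ncol = S)
  for (i in seq_along(taxa)) {
    ch <- strsplit(aln[[taxa[i]]], "")[[1L]]
    bits <- IUPAC_BITS[ch]
    if (anyNA(bits))
      stop("unknown residue '", ch[which(is.na(bits))[1L]], "' in sequence ", taxa[i])
    m[i, ] <- unname(bits)
  }
  m
}

## Compress alignment columns into unique site patterns with counts.
## Returns list(states = ntaxa x P matrix, weights = numeric P).
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  idx <- which(!duplicated(key))
  w <- as.numeric(table(factor(key, levels = key[idx])))
  list(states = states[, idx, drop = FALSE], weights = w)
}

## Site-pattern data bound to a fixed taxon ordering; the common input of the
## likelihood and parsimony engines.
make_site_data <- function(aln, taxa) {
  enc <- encode_alignment(aln, taxa)
  pat <- compress_patterns(enc)
  list(taxa = taxa, states = pat$states, weights = pat$weights,
       nsites = ncol(enc))
}
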