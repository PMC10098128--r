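# Nucleotide alignments are stored as character matrices (taxa x sites,
# uppercase IUPAC), class "nuc_alignment". Ambiguity codes are kept as-is and
# interpreted as state subsets by the likelihood machinery; '-' and '?' denote
# full ambiguity (gap).

# bitmask encoding of IUPAC states over (A=1, C=2, G=4, T=8)
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 15L, `?` = 15L
)

#' Construct a nucleotide alignment
#'
#' @param x character matrix (taxa in rows, sites in columns) or a named
#'   character vector of equal-length sequences.
#' @return An object of class `nuc_alignment`: an uppercase character matrix
#'   with unique, whitespace-normalised taxon row names.
#' @details Taxon names are normalised by stripping surrounding whitespace and
#'   replacing internal runs of whitespace with underscores; a collision after
#'   normalisation is an error. Every character must be an IUPAC nucleotide
#'   code, `-` or `?`.
#' @export
nuc_alignment <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    labs <- names(x)
    if (is.null(labs)) stop("sequences must be named by taxon")
    seqs <- strsplit(toupper(x), "", fixed = TRUE)
    len <- lengths(seqs)
    if (length(unique(len)) != 1L)
      stop("alignment shape error: sequences have unequal lengths (",
           paste(unique(len), collapse = ", "), ")")
    x <- matrix("", nrow = length(seqs), ncol = len[1L])
    for (i in seq_along(seqs)) x[i, ] <- seqs[[i]]
    rownames(x) <- labs
  }
  if (!is.matrix(x) || !is.character(x)) stop("expected a character matrix")
  if (ncol(x) < 1L) stop("alignment must have at least one site")
  labs <- normalize_taxon_labels(rownames(x))
  if (anyDuplicated(labs))
    stop("identity error: duplicate taxon labels after normalisation: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  x[] <- toupper(x)
  bad <- !(as.vector(x) %in% names(.iupac_mask))
  if (any(bad)) {
    i1 <- which(bad)[1L]
    r <- (i1 - 1L) %% nrow(x) + 1L
    co <- (i1 - 1L) %/% nrow(x) + 1L
    stop("alphabet error: illegal character '", x[r, co],
         "' in taxon '", labs[r], "' at site ", co)
  }
  rownames(x) <- labs
  structure(x, class = c("nuc_alignment", "matrix", "array"))
}

normalize_taxon_labels <- function(labs) {
  if (is.null(labs) || any(!nzchar(trimws(labs))))
    stop("taxon labels must be non-empty")
  gsub("[[:space:]]+", "_", trimws(labs))
}

#' @export
print.nuc_alignment <- function(x, ...) {
  cat("Nucleotide alignment: ", nrow(x), " taxa, ", ncol(x), " sites\n",
      sep = "")
  show <- utils::head(rownames(x), 6L)
  for (lab in show) {
    s <- paste(x[lab, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", lab, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more taxa)\n", sep = "")
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln a `nuc_alignment`.
#' @return Integer site count.
#' @export
n_sites <- function(aln) ncol(aln)

#' Read a FASTA alignment
#'
#' @param file path to a FASTA file, or `text` may be given instead.
#' @param text optional character scalar holding FASTA content.
#' @return A [nuc_alignment()].
#' @export
read_fasta <- function(file, text = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1L]], ">"))
    stop("not a FASTA file: first record must start with '>'")
  hdr <- startsWith(lines, ">")
  labs <- sub("^>", "", lines[hdr])
  # keep full header line as the label (normalisation joins words)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(s) paste(gsub("[[:space:]]", "", s), collapse = ""),
                 character(1L))
  if (length(seqs) != length(labs)) stop("FASTA record without sequence")
  names(seqs) <- labs
  nuc_alignment(seqs)
}

#' Write a FASTA alignment
#'
#' @param aln a `nuc_alignment`.
#' @param file output path.
#' @param width sequence line width (default 70).
#' @return Invisibly, `file`.
#' @export
write_fasta <- function(aln, file, width = 70L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

# integer bitmask matrix (taxa x sites) for likelihood computation
alignment_masks <- function(aln) {
  m <- matrix(.iupac_mask[aln], nrow = nrow(aln))
  rownames(m) <- rownames(aln)
  m
}

#' Per-taxon base counts
#'
#' Counts unambiguous A, C, G and T states per taxon; gaps and all ambiguity
#' codes are excluded. This is the sufficient statistic of the compositional
#' shift model.
#'
#' @param aln a `nuc_alignment`.
#' @return Integer matrix (taxa x 4) with columns A, C, G, T and an attribute
#'   `total` giving per-taxon unambiguous site counts.
#' @export
tip_base_counts <- function(aln) {
  out <- matrix(0L, nrow = nrow(aln), ncol = 4L,
                dimnames = list(rownames(aln), c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T"))
    out[, b] <- rowSums(aln == b | (b == "T" & aln == "U"))
  attr(out, "total") <- rowSums(out)
  out
}
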