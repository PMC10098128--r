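# A partition scheme is an ordered set of named, disjoint site-index sets
# covering (when complete) all alignment columns. Site indices are stored as
# 1-based R integer vectors; file formats use 1-based inclusive ranges, so the
# file boundary is the single conversion point.

#' Construct a partition scheme
#'
#' @param sites named list of integer site-index vectors (1-based).
#' @param n_total optional total site count; when given, the partitions must
#'   cover `1:n_total` exactly.
#' @return An object of class `partition_scheme`.
#' @export
partition_scheme <- function(sites, n_total = NULL) {
  if (!is.list(sites) || !length(sites)) stop("usage error: need >= 1 partition")
  nm <- names(sites)
  if (is.null(nm) || any(!nzchar(nm))) stop("partitions must be named")
  if (anyDuplicated(nm))
    stop("duplicate partition names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sites <- lapply(sites, function(s) sort(unique(as.integer(s))))
  all_idx <- unlist(sites, use.names = FALSE)
  if (anyDuplicated(all_idx))
    stop("overlap error: partitions share sites (e.g. site ",
         all_idx[duplicated(all_idx)][1L], ")")
  if (any(all_idx < 1L)) stop("site indices must be >= 1")
  if (!is.null(n_total)) {
    missing <- setdiff(seq_len(n_total), all_idx)
    if (length(missing) || any(all_idx > n_total))
      stop("coverage error: partitions do not cover 1..", n_total, " exactly")
  }
  structure(list(names = nm, sites = unname(sites)),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme with", length(x$names), "partitions,",
      sum(lengths(x$sites)), "sites\n")
  for (i in seq_len(min(10L, length(x$names))))
    cat(sprintf("  %-15s %d sites\n", x$names[i], length(x$sites[[i]])))
  if (length(x$names) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
length.partition_scheme <- function(x) length(x$names)

#' Parse a partition definition file
#'
#' Supports the RAxML dialect (`DNA, name = 1-450` with optional
#' comma-separated ranges) and NEXUS `charset` statements
#' (`charset g1 = 1-3;`). File coordinates are 1-based inclusive.
#'
#' @param text character vector of lines, or a scalar with embedded newlines.
#' @param dialect `"raxml"` or `"nexus_charsets"`.
#' @param n_total optional declared total length; when given, coverage is
#'   validated (strict mode).
#' @return A [partition_scheme()].
#' @export
parse_partition_file <- function(text, dialect = c("raxml", "nexus_charsets"),
                                 n_total = NULL) {
  dialect <- match.arg(dialect)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- switch(dialect,
    raxml = {
      lines <- grep("=", lines, fixed = TRUE, value = TRUE)
      lapply(lines, function(ln) {
        ln <- sub("^[A-Za-z0-9]+\\s*,\\s*", "", ln)  # drop "DNA," model tag
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("cannot parse partition line: ", ln)
        list(name = trimws(kv[1L]), ranges = trimws(kv[2L]))
      })
    },
    nexus_charsets = {
      lines <- grep("^charset\\b", lines, ignore.case = TRUE, value = TRUE)
      if (!length(lines)) stop("no charset statements found")
      lapply(lines, function(ln) {
        ln <- sub(";\\s*$", "", sub("^charset\\s+", "", ln, ignore.case = TRUE))
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("cannot parse charset: ", ln)
        list(name = trimws(kv[1L]), ranges = trimws(kv[2L]))
      })
    })
  sites <- lapply(entries, function(e) {
    ranges <- strsplit(e$ranges, "[,[:space:]]+")[[1L]]
    ranges <- ranges[nzchar(ranges)]
    unlist(lapply(ranges, function(r) {
      ab <- as.integer(strsplit(r, "-", fixed = TRUE)[[1L]])
      if (length(ab) == 1L) ab else {
        if (ab[2L] < ab[1L]) stop("descending range: ", r)
        seq.int(ab[1L], ab[2L])
      }
    }))
  })
  names(sites) <- vapply(entries, `[[`, "", "name")
  partition_scheme(sites, n_total = n_total)
}

#' Write a partition scheme in the RAxML dialect
#' @param scheme a `partition_scheme` whose partitions are contiguous ranges.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_partition_file <- function(scheme, file) {
  lines <- vapply(seq_along(scheme$names), function(i) {
    s <- scheme$sites[[i]]
    # emit maximal runs as ranges
    brk <- c(0L, which(diff(s) != 1L), length(s))
    runs <- vapply(seq_len(length(brk) - 1L), function(j) {
      a <- s[brk[j] + 1L]; b <- s[brk[j + 1L]]
      if (a == b) as.character(a) else paste0(a, "-", b)
    }, character(1L))
    paste0("DNA, ", scheme$names[i], " = ", paste(runs, collapse = ","))
  }, character(1L))
  writeLines(lines, file)
  invisible(file)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Builds the union-of-taxa supermatrix: taxa missing from a gene are filled
#' with gaps (`-`, full ambiguity) for that gene's columns. The returned
#' scheme has one partition per input gene, in input order.
#'
#' @param alignments named list of `nuc_alignment` objects (names become
#'   partition names; unnamed inputs get `gene1`, `gene2`, ...).
#' @return List with elements `alignment` (the supermatrix) and `scheme`
#'   (a [partition_scheme()]).
#' @export
concatenate_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("usage error: empty alignment list")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    names(alignments) <- paste0("gene", seq_along(alignments))
  taxa <- unique(unlist(lapply(alignments, rownames)))
  widths <- vapply(alignments, ncol, integer(1L))
  total <- sum(widths)
  sup <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  off <- 0L
  sites <- vector("list", length(alignments))
  for (g in seq_along(alignments)) {
    a <- alignments[[g]]
    cols <- off + seq_len(ncol(a))
    sup[rownames(a), cols] <- unclass(a)
    sites[[g]] <- cols
    off <- off + ncol(a)
  }
  names(sites) <- names(alignments)
  list(alignment = nuc_alignment(sup),
       scheme = partition_scheme(sites, n_total = total))
}

#' Per-gene taxon occupancy
#'
#' @param alignments named list of `nuc_alignment` objects.
#' @return Data frame with gene, taxa present, total taxa in the union, and
#'   the occupancy fraction.
#' @export
occupancy_report <- function(alignments) {
  taxa <- unique(unlist(lapply(alignments, rownames)))
  data.frame(gene = names(alignments),
             n_taxa = vapply(alignments, nrow, integer(1L)),
             n_total = length(taxa),
             occupancy = vapply(alignments, nrow, integer(1L)) / length(taxa),
             row.names = NULL)
}

#' Extract the columns of one partition as an alignment
#' @param aln a `nuc_alignment`.
#' @param scheme a `partition_scheme`.
#' @param which partition name or index.
#' @param drop_empty drop taxa that are entirely gap/ambiguous in the subset
#'   (default TRUE: a taxon absent from a gene carries no data for it).
#' @return A `nuc_alignment` restricted to the partition's sites.
#' @export
partition_columns <- function(aln, scheme, which, drop_empty = TRUE) {
  i <- if (is.character(which)) match(which, scheme$names) else as.integer(which)
  if (is.na(i) || i < 1L || i > length(scheme$names))
    stop("unknown partition: ", which)
  s <- scheme$sites[[i]]
  if (max(s) > ncol(aln)) stop("partition outside alignment bounds")
  sub <- unclass(aln)[, s, drop = FALSE]
  if (drop_empty) {
    keep <- apply(sub, 1L, function(r) any(!(r %in% c("-", "?", "N"))))
    if (any(keep)) sub <- sub[keep, , drop = FALSE]
  }
  nuc_alignment(sub)
}
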