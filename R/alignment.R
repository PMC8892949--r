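#' Read a multiple sequence alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP into an uppercase character
#' matrix (rows = taxa, columns = sites). The working alphabet is
#' `A, C, G, T, -, N`; any other IUPAC code (ambiguities such as `R`, `Y`,
#' and `?`) is collapsed to `N` with a warning, mirroring the treatment of
#' nonnucleotide characters as missing data.
#'
#' @param path Input file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return Character matrix with taxon rownames.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0) stop("no FASTA headers found in ", path)
    taxa <- sub("^>\\s*", "", lines[hdr])
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
    }, character(1))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    ntax <- as.integer(head_fields[1])
    body <- lines[-1]
    if (length(body) != ntax) stop("expected ", ntax, " sequence lines, got ",
                                   length(body))
    parts <- strsplit(trimws(body), "\\s+")
    taxa <- vapply(parts, `[[`, character(1), 1)
    seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  }
  .alignment_from_strings(taxa, seqs)
}

.alignment_from_strings <- function(taxa, seqs) {
  if (anyDuplicated(taxa)) {
    stop("duplicate taxa: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("ragged rows: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- taxa
  bad <- !(m %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warning(sum(bad), " ambiguity/other character(s) collapsed to N")
    m[bad] <- "N"
  }
  m
}

#' Write a multiple sequence alignment
#'
#' @param aln Character matrix with taxon rownames.
#' @param path Output file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(aln, 1, paste, collapse = "")
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", rownames(aln)), seqs))
  } else {
    lines <- c(paste(nrow(aln), ncol(aln)),
               paste(format(rownames(aln), width = max(nchar(rownames(aln)))),
                     seqs, sep = "  "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `DNA, name = a-b` with 1-based inclusive coordinates are
#' converted to the package-internal convention of 0-based half-open
#' intervals, so `DNA, g1 = 1-300` becomes `[0, 300)`.
#'
#' @param path Partition file path.
#' @param n_sites Optional alignment width for bounds checking.
#' @return Tibble with columns `gene`, `start`, `end` (0-based half-open).
#' @export
read_partitions <- function(path, n_sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines,
                  regexec("^\\s*\\S+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
                          lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable partition line(s): ",
                     paste(lines[bad], collapse = " | "))
  parts <- tibble(
    gene = vapply(m, `[[`, character(1), 2),
    start = vapply(m, function(x) as.integer(x[3]) - 1L, integer(1)),
    end = vapply(m, function(x) as.integer(x[4]), integer(1))
  )
  validate_partitions(parts, n_sites)
  parts
}

#' @rdname read_partitions
#' @param parts Partition tibble as returned by [read_partitions()].
#' @export
write_partitions <- function(parts, path) {
  writeLines(sprintf("DNA, %s = %d-%d", parts$gene, parts$start + 1L,
                     parts$end), path)
  invisible(path)
}

#' Validate a partition table
#'
#' Checks nonempty, non-overlapping, in-bounds intervals.
#'
#' @param parts Tibble with `gene`, `start`, `end` (0-based half-open).
#' @param n_sites Optional alignment width.
#' @return `parts`, invisibly.
#' @export
validate_partitions <- function(parts, n_sites = NULL) {
  if (any(parts$end <= parts$start)) stop("empty partition interval")
  if (any(parts$start < 0)) stop("negative partition start")
  if (!is.null(n_sites) && any(parts$end > n_sites)) {
    stop("partition exceeds alignment bounds (", n_sites, " sites)")
  }
  o <- order(parts$start)
  s <- parts$start[o]; e <- parts$end[o]
  if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
    stop("overlapping partitions: ",
         paste(parts$gene[o][c(which(s[-1] < e[-length(e)]) + 1L)],
               collapse = ", "))
  }
  invisible(parts)
}

# encode alignment to integers: A=1 C=2 G=3 T=4, everything else NA
.encode_alignment <- function(aln) {
  code <- match(aln, c("A", "C", "G", "T"))
  dim(code) <- dim(aln)
  rownames(code) <- rownames(aln)
  code
}

#' Extract one gene's columns from a supermatrix
#'
#' @param aln Character (or encoded) matrix.
#' @param parts Partition tibble.
#' @param gene Gene name present in `parts$gene`.
#' @return The sub-matrix of the gene's columns.
#' @export
gene_columns <- function(aln, parts, gene) {
  i <- match(gene, parts$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  aln[, (parts$start[i] + 1L):parts$end[i], drop = FALSE]
}

#' Mean pairwise-identity conservation score
#'
#' A transparent per-gene conservation statistic: for every column, the mean
#' pairwise character identity among rows holding an unambiguous nucleotide
#' (`A/C/G/T`); the score is the mean over columns with at least two such
#' residues. Lies in `[0, 1]`; columns of a single repeated character score 1.
#'
#' @param aln Character matrix (one gene's alignment).
#' @return A scalar in `[0, 1]`, or `NA` if no column is scorable.
#' @export
conservation_score <- function(aln) {
  enc <- .encode_alignment(aln)
  col_score <- function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2) return(NA_real_)
    counts <- tabulate(col, 4L)
    same <- sum(counts * (counts - 1) / 2)
    same / (n * (n - 1) / 2)
  }
  scores <- apply(enc, 2, col_score)
  if (all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' Clade map constructor
#'
#' Binds a taxon-to-clade assignment table with a designated outgroup clade.
#'
#' @param assignments Data frame with columns `taxon` and `clade`.
#' @param outgroup Name of the outgroup clade (must appear in `clade`).
#' @return A tibble of class `clade_map` with attribute `outgroup`.
#' @export
clade_map <- function(assignments, outgroup) {
  df <- as_tibble(assignments[, c("taxon", "clade")])
  if (anyDuplicated(df$taxon)) {
    stop("taxa assigned to more than one clade: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  }
  if (!outgroup %in% df$clade) stop("outgroup clade '", outgroup,
                                    "' has no taxa")
  if (length(setdiff(unique(df$clade), outgroup)) < 2) {
    stop("need at least two ingroup clades")
  }
  structure(df, class = c("clade_map", class(df)), outgroup = outgroup)
}

#' @rdname clade_map
#' @param x A `clade_map`.
#' @export
ingroup_clades <- function(x) {
  setdiff(unique(x$clade), attr(x, "outgroup"))
}

#' @rdname clade_map
#' @export
outgroup_clade <- function(x) attr(x, "outgroup")

#' @rdname clade_map
#' @param clade Clade label.
#' @export
clade_taxa <- function(x, clade) x$taxon[x$clade %in% clade]

#' Read/write a clade map as TSV
#'
#' The TSV has columns `taxon`, `clade`; the outgroup clade is flagged with a
#' trailing `*` on its label (stripped on read).
#'
#' @param path File path.
#' @return A `clade_map` (read) or `path` invisibly (write).
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  star <- grepl("\\*$", df$clade)
  if (!any(star)) stop("no clade flagged as outgroup ('*' suffix)")
  df$clade <- sub("\\*$", "", df$clade)
  clade_map(df, outgroup = unique(df$clade[star]))
}

#' @rdname read_clade_map
#' @param x A `clade_map`.
#' @export
write_clade_map <- function(x, path) {
  df <- as.data.frame(x)
  og <- attr(x, "outgroup")
  df$clade <- ifelse(df$clade == og, paste0(df$clade, "*"), df$clade)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
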