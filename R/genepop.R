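#' Read a GenePop file
#'
#' Parses the GenePop text dialect used for published microsatellite panels:
#' a title line, locus names (one per line or comma-separated), `Pop` markers,
#' and one line per individual of the form `id , 010012 0305 ...` with two- or
#' three-digit allele codes (auto-detected per file) and `0` codes marking
#' missing alleles. Populations are pooled into one dataset; the population of
#' origin is kept in `$pop`.
#'
#' @param path path to a GenePop file.
#' @param motif_bp motif length(s) in bp assigned to the loci (recycled);
#'   GenePop carries no motif metadata.
#' @param encoding allele size encoding declared for the file.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, motif_bp = 2L,
                         encoding = c("bp", "repeat_units")) {
  encoding <- match.arg(encoding)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("malformed GenePop file: fewer than 3 lines")
  title <- lines[1]
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("malformed GenePop header: no 'Pop' line after locus names")
  locus_lines <- lines[2:(first_pop - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  if (anyDuplicated(locus_names)) stop("duplicate locus names in header")
  nl <- length(locus_names)

  ids <- character(); pops <- integer()
  rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (is_pop[i]) { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i, ": expected 'id , genotypes' with a comma separator")
    id <- trimws(paste(parts[-length(parts)], collapse = ","))
    gts <- strsplit(trimws(parts[length(parts)]), "\\s+")[[1]]
    gts <- gts[nzchar(gts)]
    if (length(gts) != nl)
      stop("line ", i, ": ", length(gts), " genotypes for ", nl, " loci")
    if (!all(grepl("^[0-9]+$", gts)))
      stop("line ", i, ": non-numeric genotype code")
    w <- unique(nchar(gts)) / 2
    if (length(unique(nchar(gts))) != 1 || !(w[1] %in% c(2, 3)))
      stop("line ", i, ": inconsistent allele-code width (need 4- or 6-digit genotypes)")
    if (is.na(width)) width <- as.integer(w[1])
    else if (width != w[1])
      stop("line ", i, ": allele-code width differs from earlier lines")
    a1 <- as.integer(substr(gts, 1, width))
    a2 <- as.integer(substr(gts, width + 1, 2 * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    # a genotype with either allele coded 0 is treated as missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, pop_idx)
    rows1[[length(rows1) + 1L]] <- a1
    rows2[[length(rows2) + 1L]] <- a2
  }
  if (length(ids) == 0) stop("no individuals found")
  m1 <- do.call(rbind, rows1); m2 <- do.call(rbind, rows2)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rownames(m1) <- rownames(m2) <- ids
  loci <- data.frame(id = locus_names,
                     motif_bp = as.integer(rep_len(motif_bp, nl)))
  genotype_dataset(title, m1, m2, loci, encoding = encoding,
                   pop = factor(pops))
}

#' Write a GenePop file
#'
#' Emits a dataset in the GenePop dialect accepted by [read_genepop()], using
#' fixed-width allele codes (`000.../0000` for missing genotypes). Reading the
#' file back reproduces the dataset's genotypes, individual ids, locus names
#' and population labels.
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param width allele code width (2 or 3 digits).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, width = 3L) {
  if (!width %in% c(2L, 3L)) stop("width must be 2 or 3")
  maxa <- suppressWarnings(max(c(ds$allele1, ds$allele2), na.rm = TRUE))
  if (is.finite(maxa) && maxa > 10^width - 1)
    stop("allele size ", maxa, " exceeds ", width, "-digit code width")
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = width, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(ds$species_id, con)
  writeLines(ds$loci$id, con)
  pop <- ds$pop %||% factor(rep(1L, n_individuals(ds)))
  for (p in levels(factor(pop))) {
    writeLines("Pop", con)
    for (i in which(as.character(pop) == p)) {
      g <- paste0(fmt(ds$allele1[i, ]), fmt(ds$allele2[i, ]))
      writeLines(paste(ds$individuals[i], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
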