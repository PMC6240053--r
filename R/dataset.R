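#' Diploid microsatellite genotype dataset
#'
#' Container for a single-species panel of diploid microsatellite genotypes:
#' an individuals-by-loci matrix of unordered allele-size pairs with per-locus
#' metadata. Allele sizes are positive integers, either fragment sizes in base
#' pairs (`encoding = "bp"`) or repeat units (`encoding = "repeat_units"`).
#' Missing genotypes are `NA` in both allele slots.
#'
#' @param species_id character scalar naming the dataset.
#' @param allele1,allele2 integer matrices (individuals x loci) holding the two
#'   allele sizes per genotype; pair order is irrelevant and is canonicalised
#'   so that `allele1 <= allele2`.
#' @param loci data.frame with columns `id` (unique locus names), `motif_bp`
#'   (repeat motif length in bp, 1--6) and optionally `encoding`.
#' @param encoding `"bp"` or `"repeat_units"`, applied to all loci.
#' @param pop optional factor of population labels per individual (kept as
#'   metadata; all statistics treat the dataset as one population).
#'
#' @return An object of class `genotype_dataset` with elements `species_id`,
#'   `loci`, `individuals`, `allele1`, `allele2`, `encoding`, `pop`.
#' @export
genotype_dataset <- function(species_id, allele1, allele2, loci,
                             encoding = c("bp", "repeat_units"), pop = NULL) {
  encoding <- match.arg(encoding)
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  if (!identical(dim(allele1), dim(allele2)))
    stop("allele matrices must have identical dimensions")
  if (is.null(loci$id)) stop("loci must have an 'id' column")
  loci$id <- as.character(loci$id)
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  if (is.null(loci$motif_bp)) loci$motif_bp <- 2L
  if (any(loci$motif_bp < 1)) stop("motif_bp must be >= 1")
  if (nrow(loci) != ncol(allele1))
    stop("number of loci does not match genotype matrix columns")
  loci$encoding <- encoding
  if (is.null(rownames(allele1)))
    rownames(allele1) <- rownames(allele2) <- paste0("ind_", seq_len(nrow(allele1)))
  colnames(allele1) <- colnames(allele2) <- loci$id
  # canonicalise unordered pairs
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  miss_mismatch <- xor(is.na(allele1), is.na(allele2))
  if (any(miss_mismatch))
    stop("half-missing genotypes found; both alleles must be NA or neither")
  if (any(allele1 < 1, na.rm = TRUE))
    stop("allele sizes must be positive")
  ds <- structure(
    list(species_id = as.character(species_id), loci = loci,
         individuals = rownames(allele1), allele1 = allele1,
         allele2 = allele2, encoding = encoding, pop = pop),
    class = "genotype_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  typed <- colSums(!is.na(ds$allele1))
  if (any(typed == 0))
    stop("locus with no non-missing genotypes: ",
         paste(ds$loci$id[typed == 0], collapse = ", "))
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Microsatellite genotype dataset:", x$species_id, "\n")
  cat(" ", length(x$individuals), "individuals x", nrow(x$loci), "loci;",
      "allele encoding:", x$encoding, "\n")
  miss <- mean(is.na(x$allele1))
  cat("  missing genotypes:", sprintf("%.1f%%", 100 * miss), "\n")
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  st <- do.call(rbind, lapply(object$loci$id, function(l)
    as.data.frame(locus_stats(object, l))))
  st <- cbind(locus = object$loci$id, st)
  rownames(st) <- NULL
  st
}

#' Number of individuals and loci
#' @param ds a [genotype_dataset()].
#' @return integer scalar.
#' @export
n_individuals <- function(ds) length(ds$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) nrow(ds$loci)

#' Subset a genotype dataset
#'
#' Keeps the given individuals and/or loci, preserving order, and re-checks
#' dataset invariants (every retained locus must keep at least one non-missing
#' genotype). Used for largest-cluster reruns (cluster labels supplied
#' externally) and for dropping HWE-deviating loci.
#'
#' @param x a [genotype_dataset()].
#' @param individuals,loci character vectors of ids to keep (default: all).
#' @param ... ignored.
#' @return A [genotype_dataset()].
#' @export
subset.genotype_dataset <- function(x, individuals = NULL, loci = NULL, ...) {
  ind <- individuals %||% x$individuals
  loc <- loci %||% x$loci$id
  if (length(ind) == 0 || length(loc) == 0) stop("empty selection")
  if (!all(ind %in% x$individuals)) stop("unknown individual id(s)")
  if (!all(loc %in% x$loci$id)) stop("unknown locus id(s)")
  ind <- x$individuals[x$individuals %in% ind]
  loc <- x$loci$id[x$loci$id %in% loc]
  genotype_dataset(
    x$species_id,
    x$allele1[ind, loc, drop = FALSE], x$allele2[ind, loc, drop = FALSE],
    x$loci[match(loc, x$loci$id), , drop = FALSE],
    encoding = x$encoding,
    pop = if (!is.null(x$pop)) x$pop[match(ind, x$individuals)])
}

#' Convert allele sizes from base pairs to repeat units
#'
#' Estimates each locus's repeat motif as the modal gap among its sorted
#' distinct allele sizes (falling back to the declared `motif_bp` for
#' monomorphic loci) and maps every allele to
#' `round((size - min_size)/motif) + offset` repeat units. Off-lattice alleles
#' (sizes not conforming to the motif periodicity) are retained via nearest-
#' unit rounding, an approximation mirroring how mixed published panels are
#' handled in practice. Datasets already in repeat units are returned
#' unchanged.
#'
#' @param ds a [genotype_dataset()].
#' @return A [genotype_dataset()] with `encoding = "repeat_units"`.
#' @export
to_repeat_units <- function(ds) {
  if (ds$encoding == "repeat_units") return(ds)
  a1 <- ds$allele1; a2 <- ds$allele2
  for (j in seq_len(n_loci(ds))) {
    sizes <- sort(unique(c(a1[, j], a2[, j])))
    sizes <- sizes[!is.na(sizes)]
    if (length(sizes) < 2) {
      motif <- ds$loci$motif_bp[j]
      if (motif < 1) stop("declared motif_bp must be >= 1 for monomorphic locus ",
                          ds$loci$id[j])
    } else {
      gaps <- diff(sizes)
      tab <- table(gaps)
      motif <- as.integer(names(tab)[which.max(tab)])  # ties: smallest gap
    }
    offset <- as.integer(round(sizes[1] / motif))
    if (offset < 1L) offset <- 1L
    u1 <- as.integer(round((a1[, j] - sizes[1]) / motif)) + offset
    u2 <- as.integer(round((a2[, j] - sizes[1]) / motif)) + offset
    a1[, j] <- u1; a2[, j] <- u2
    ds$loci$motif_bp[j] <- motif
  }
  genotype_dataset(ds$species_id, a1, a2, ds$loci,
                   encoding = "repeat_units", pop = ds$pop)
}
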