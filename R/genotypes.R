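#' Genotype matrix for multiallelic (SSR) markers
#'
#' `geno_matrix()` builds the package's universal input object: a set of
#' diploid individuals genotyped at multiallelic loci, with two allele slots
#' per cell. Allele codes are positive integer fragment sizes in bp; a null
#' allele (a codominantly scored non-amplifying variant) is the distinct
#' state `0`; a missing call is `NA`. Both slots of a cell must be missing
#' or neither: half-missing cells are rejected.
#'
#' Heterozygote allele order carries no information; cells are canonicalised
#' so that slot 1 <= slot 2 (the null state sorts first).
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele codes with
#'   identical dimensions and dimnames. `NA` = missing, `0` = null allele,
#'   positive values = fragment size in bp.
#' @param pop Optional character vector of population labels, one per
#'   individual (recycled names are not allowed; order follows rows).
#' @return An object of class `geno_matrix`.
#' @examples
#' a1 <- matrix(c(100L, 100L, 100L, 120L), 2, 2,
#'              dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' a2 <- matrix(c(100L, 120L, 120L, 120L), 2, 2, dimnames = dimnames(a1))
#' gm <- geno_matrix(a1, a2, pop = c("A", "A"))
#' gm
#' @export
geno_matrix <- function(a1, a2, pop = NULL) {
  if (!is.matrix(a1) || !is.matrix(a2) || !all(dim(a1) == dim(a2))) {
    stop("`a1` and `a2` must be matrices of identical dimension", call. = FALSE)
  }
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  rn <- rownames(a1) %||% (if (nrow(a1)) paste0("ind", seq_len(nrow(a1))) else character(0))
  cn <- colnames(a1) %||% (if (ncol(a1)) paste0("locus", seq_len(ncol(a1))) else character(0))
  dimnames(a1) <- list(rn, cn)
  dimnames(a2) <- dimnames(a1)
  if (anyDuplicated(rownames(a1))) stop("individual identifiers must be unique", call. = FALSE)
  if (anyDuplicated(colnames(a1))) stop("locus identifiers must be unique", call. = FALSE)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing cell at individual '%s', locus '%s'",
                 rownames(a1)[idx[1]], colnames(a1)[idx[2]]), call. = FALSE)
  }
  if (any(a1 < 0, na.rm = TRUE) || any(a2 < 0, na.rm = TRUE)) {
    stop("allele codes must be >= 0 (0 = null allele)", call. = FALSE)
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  if (!is.null(pop)) {
    pop <- as.character(pop)
    if (length(pop) != nrow(a1)) stop("`pop` must have one label per individual", call. = FALSE)
    names(pop) <- rownames(a1)
  }
  structure(list(a1 = a1, a2 = a2, pop = pop), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci\n",
              nrow(x$a1), ncol(x$a1)))
  nm <- sum(is.na(x$a1))
  nn <- sum(x$a1 == 0L, na.rm = TRUE) + sum(x$a2 == 0L, na.rm = TRUE)
  cat(sprintf("  missing cells: %d (%.1f%%), null allele copies: %d\n",
              nm, 100 * nm / length(x$a1), nn))
  if (!is.null(x$pop)) {
    tb <- table(x$pop)
    cat("  populations: ", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$a1)

#' Individual and locus identifiers
#' @param gm A [geno_matrix()].
#' @return Character vector of identifiers.
#' @export
individuals <- function(gm) rownames(gm$a1)

#' @rdname individuals
#' @export
loci <- function(gm) colnames(gm$a1)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i,j Individual / locus indices (any standard matrix index).
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  geno_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
              pop = if (!is.null(x$pop)) unname(x$pop[i]))
}

#' @export
as_tibble.geno_matrix <- function(x, ...) {
  out <- tibble::tibble(
    individual = rep(rownames(x$a1), times = ncol(x$a1)),
    locus = rep(colnames(x$a1), each = nrow(x$a1)),
    allele1 = as.vector(x$a1),
    allele2 = as.vector(x$a2)
  )
  if (!is.null(x$pop)) {
    out$population <- rep(unname(x$pop), times = ncol(x$a1))
  }
  out
}

#' @method all.equal geno_matrix
#' @export
all.equal.geno_matrix <- function(target, current, ...) {
  msgs <- character()
  if (!identical(dimnames(target$a1), dimnames(current$a1))) msgs <- c(msgs, "dimnames differ")
  if (!identical(unname(target$a1), unname(current$a1)) ||
      !identical(unname(target$a2), unname(current$a2))) msgs <- c(msgs, "allele calls differ")
  tp <- if (is.null(target$pop)) NULL else unname(target$pop)
  cp <- if (is.null(current$pop)) NULL else unname(current$pop)
  if (!identical(tp, cp)) msgs <- c(msgs, "population labels differ")
  if (length(msgs)) msgs else TRUE
}

# population labels as a named vector, with a fallback single population
.pop_of <- function(gm, grouping = NULL) {
  if (is.null(grouping)) grouping <- gm$pop
  if (is.null(grouping)) {
    grouping <- stats::setNames(rep("pop1", nrow(gm$a1)), individuals(gm))
  }
  if (is.null(names(grouping))) names(grouping) <- individuals(gm)
  missing_ind <- setdiff(names(grouping), individuals(gm))
  if (length(missing_ind)) {
    stop("grouping names unknown individuals: ", paste(missing_ind, collapse = ", "),
         call. = FALSE)
  }
  grouping
}

#' Per-population allele frequencies
#'
#' Counts allele copies per (population, locus), excluding missing cells;
#' the null allele (`0`) is a real allele class and contributes copies like
#' any fragment-size allele. Populations with no called cells at a locus get
#' a single flagged row (`defined = FALSE`) rather than an error.
#'
#' @param gm A [geno_matrix()].
#' @param grouping Optional named character vector individual -> population;
#'   defaults to the matrix's own labels, or a single pooled population.
#' @return A tibble with columns `population`, `locus`, `allele` (integer,
#'   0 = null), `count`, `freq`, `n_genes` and `defined`.
#' @examples
#' gm <- sim_flaxlike(seed = 1, n_loci = 5)$genotypes
#' allele_frequencies(gm)
#' @export
allele_frequencies <- function(gm, grouping = NULL) {
  grouping <- .pop_of(gm, grouping)
  ind <- names(grouping)
  sub <- gm[ind, ]
  pops <- unname(grouping)
  long <- tibble::tibble(
    population = rep(rep(pops, times = ncol(sub$a1)), 2L),
    locus = rep(rep(colnames(sub$a1), each = nrow(sub$a1)), 2L),
    allele = c(as.vector(sub$a1), as.vector(sub$a2))
  )
  counts <- long |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$population, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n_genes = sum(.data$count),
                  freq = .data$count / .data$n_genes,
                  defined = TRUE) |>
    dplyr::ungroup()
  # flag (population, locus) combinations with zero called copies
  grid <- tidyr::expand_grid(population = unique(pops), locus = colnames(sub$a1))
  empty <- dplyr::anti_join(grid, counts, by = c("population", "locus")) |>
    dplyr::mutate(allele = NA_integer_, count = 0L, n_genes = 0L,
                  freq = NA_real_, defined = FALSE)
  dplyr::bind_rows(counts, empty) |>
    dplyr::arrange(.data$population, .data$locus, .data$allele) |>
    dplyr::select("population", "locus", "allele", "count", "freq",
                  "n_genes", "defined")
}

#' Minor allele frequency
#'
#' Frequency of the rarest segregating allele at each (population, locus);
#' 0 for a monomorphic locus. Undefined frequency entries raise an error.
#'
#' @param freqs An allele-frequency tibble from [allele_frequencies()].
#' @param locus Optional locus identifier(s) to restrict to.
#' @return Tibble with `population`, `locus`, `maf`.
#' @export
minor_allele_frequency <- function(freqs, locus = NULL) {
  if (!is.null(locus)) {
    freqs <- dplyr::filter(freqs, .data$locus %in% !!locus)
    if (nrow(freqs) == 0) stop("locus not present in frequency table", call. = FALSE)
  }
  if (any(!freqs$defined)) {
    bad <- dplyr::filter(freqs, !.data$defined)
    stop("undefined frequencies at e.g. population '", bad$population[1],
         "', locus '", bad$locus[1], "'", call. = FALSE)
  }
  freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      maf = if (dplyr::n() < 2) 0 else min(.data$freq),
      .groups = "drop"
    )
}
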