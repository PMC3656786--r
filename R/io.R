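#' Read a multiallelic genotype file
#'
#' Three text dialects are supported, mirroring the encodings commonly used
#' for codominant SSR data:
#'
#' * `"csv"`: one row per individual; first column the individual id, an
#'   optional second column `population`, then one column per locus with
#'   cells `"a/b"` (bp sizes). `"?"` marks a missing slot, `"999"` the null
#'   allele.
#' * `"genepop"`: Genepop 4.x layout (title line, one locus name per line,
#'   `Pop` separators, `name , 0102 0304 ...`). Allele code width (2 or 3
#'   digits) is auto-detected; code 99/999 is the null allele and 00/000 a
#'   missing slot. If a sidecar `<path>.alleles.tsv` written by
#'   [write_genotypes()] is present, codes are translated back to bp sizes;
#'   otherwise the numeric codes themselves are used as allele codes.
#'   Genepop carries no population names: blocks are labelled `pop1`,
#'   `pop2`, ... in file order.
#' * `"structure"`: a header row of locus names, then two rows per
#'   individual (`id [population] allele-per-locus`), `-9` for missing.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"genepop"`, `"structure"`.
#' @return A [geno_matrix()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("csv", "genepop", "structure")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    csv = .read_csv_gm(path),
    genepop = .read_genepop_gm(path),
    structure = .read_structure_gm(path)
  )
}

#' Write a multiallelic genotype file
#'
#' Inverse of [read_genotypes()]; see that help page for the dialects.
#' Heterozygous cells are written with alleles sorted ascending. The Genepop
#' writer recodes bp sizes to 2- or 3-digit per-locus codes (width chosen to
#' fit the largest allele count) and emits the size-to-code table to
#' `<path>.alleles.tsv`; individuals are grouped into `Pop` blocks by
#' population in order of first appearance.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @param format One of `"csv"`, `"genepop"`, `"structure"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("csv", "genepop", "structure")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "geno_matrix"))
  switch(format,
    csv = .write_csv_gm(gm, path),
    genepop = .write_genepop_gm(gm, path),
    structure = .write_structure_gm(gm, path)
  )
  invisible(path)
}

.parse_cell <- function(txt, path, line_no) {
  parts <- strsplit(txt, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop(sprintf("%s:%d: malformed genotype cell '%s'", path, line_no, txt),
         call. = FALSE)
  }
  vapply(parts, function(p) {
    p <- trimws(p)
    if (p == "?") return(NA_integer_)
    if (p == "999") return(0L)
    v <- suppressWarnings(as.integer(p))
    if (is.na(v) || v < 0) {
      stop(sprintf("%s:%d: bad allele code '%s'", path, line_no, p), call. = FALSE)
    }
    v
  }, integer(1), USE.NAMES = FALSE)
}

.read_csv_gm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop(path, ": empty file", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]] |> trimws()
  has_pop <- length(header) >= 2 && tolower(header[2]) == "population"
  locus_names <- header[(if (has_pop) 3 else 2):length(header)]
  if (length(lines) == 1 || all(!nzchar(trimws(lines[-1])))) {
    a <- matrix(integer(), 0, length(locus_names),
                dimnames = list(character(), locus_names))
    return(geno_matrix(a, a))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  a1 <- a2 <- matrix(NA_integer_, n, length(locus_names))
  ids <- character(n)
  pops <- if (has_pop) character(n) else NULL
  for (i in seq_len(n)) {
    ln <- i + 1L
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]] |> trimws()
    if (length(fields) != length(header)) {
      stop(sprintf("%s:%d: expected %d fields, found %d", path, ln,
                   length(header), length(fields)), call. = FALSE)
    }
    ids[i] <- fields[1]
    if (has_pop) pops[i] <- fields[2]
    cells <- fields[(if (has_pop) 3 else 2):length(fields)]
    for (j in seq_along(cells)) {
      ab <- .parse_cell(cells[j], path, ln)
      a1[i, j] <- ab[1]
      a2[i, j] <- ab[2]
    }
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, locus_names)
  geno_matrix(a1, a2, pop = pops)
}

.format_cell <- function(x1, x2) {
  enc <- function(v) ifelse(is.na(v), "?", ifelse(v == 0L, "999", as.character(v)))
  paste0(enc(x1), "/", enc(x2))
}

.write_csv_gm <- function(gm, path) {
  if (any(gm$a1 < 0, na.rm = TRUE)) stop("unencodable negative allele code", call. = FALSE)
  has_pop <- !is.null(gm$pop)
  header <- c("id", if (has_pop) "population", loci(gm))
  rows <- vapply(seq_len(nrow(gm$a1)), function(i) {
    cells <- .format_cell(gm$a1[i, ], gm$a2[i, ])
    paste(c(individuals(gm)[i], if (has_pop) unname(gm$pop[i]), cells),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
}

.read_genepop_gm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop(path, ": truncated Genepop file", call. = FALSE)
  i <- 2L
  locus_names <- character()
  while (i <= length(lines) && !grepl("^\\s*pop\\s*$", lines[i], ignore.case = TRUE)) {
    # loci may be one per line or comma-separated
    locus_names <- c(locus_names, trimws(strsplit(lines[i], ",")[[1]]))
    i <- i + 1L
  }
  locus_names <- locus_names[nzchar(locus_names)]
  sidecar <- paste0(path, ".alleles.tsv")
  code_map <- NULL
  if (file.exists(sidecar)) {
    code_map <- utils::read.delim(sidecar, colClasses = c("character", "integer", "integer"))
  }
  ids <- character(); pops <- character(); rows1 <- list(); rows2 <- list()
  pop_idx <- 0L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L
      i <- i + 1L
      next
    }
    if (!nzchar(trimws(ln))) { i <- i + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("%s:%d: expected 'name , codes'", path, i), call. = FALSE)
    }
    name <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(locus_names)) {
      stop(sprintf("%s:%d: expected %d genotype codes, found %d", path, i,
                   length(locus_names), length(codes)), call. = FALSE)
    }
    widths <- nchar(codes)
    if (!all(widths %in% c(4L, 6L)) || length(unique(widths)) != 1) {
      stop(sprintf("%s:%d: inconsistent allele code width", path, i), call. = FALSE)
    }
    w <- widths[1] / 2L
    c1 <- as.integer(substr(codes, 1, w))
    c2 <- as.integer(substr(codes, w + 1, 2 * w))
    null_code <- if (w == 2) 99L else 999L
    decode <- function(cc, locus) {
      if (cc == 0L) return(NA_integer_)
      if (cc == null_code) return(0L)
      if (!is.null(code_map)) {
        hit <- code_map$allele[code_map$locus == locus & code_map$code == cc]
        if (length(hit) == 1) return(hit)
      }
      cc
    }
    rows1[[length(rows1) + 1L]] <- mapply(decode, c1, locus_names)
    rows2[[length(rows2) + 1L]] <- mapply(decode, c2, locus_names)
    ids <- c(ids, name)
    pops <- c(pops, paste0("pop", max(pop_idx, 1L)))
    i <- i + 1L
  }
  a1 <- do.call(rbind, rows1)
  a2 <- do.call(rbind, rows2)
  if (is.null(a1)) a1 <- a2 <- matrix(NA_integer_, 0, length(locus_names))
  dimnames(a1) <- dimnames(a2) <- list(ids, locus_names)
  geno_matrix(a1, a2, pop = if (length(pops)) pops)
}

.write_genepop_gm <- function(gm, path) {
  if (any(gm$a1 < 0, na.rm = TRUE)) stop("unencodable negative allele code", call. = FALSE)
  # per-locus size -> code table; width must also hold the null sentinel
  tabs <- lapply(seq_along(loci(gm)), function(j) {
    sizes <- sort(unique(stats::na.omit(c(gm$a1[, j], gm$a2[, j]))))
    sizes <- sizes[sizes > 0]
    data.frame(locus = rep(loci(gm)[j], length(sizes)), allele = sizes,
               code = seq_along(sizes))
  })
  code_map <- do.call(rbind, c(tabs, list(data.frame(locus = character(),
                                                     allele = integer(),
                                                     code = integer()))))
  w <- if (nrow(code_map) && max(code_map$code) > 98) 3L else 2L
  null_code <- if (w == 2) 99L else 999L
  fmt <- function(v) formatC(v, width = w, flag = "0")
  pop <- if (is.null(gm$pop)) rep("pop1", nrow(gm$a1)) else unname(gm$pop)
  out <- c(sprintf("ssrpopkit export: %d individuals, %d loci",
                   nrow(gm$a1), ncol(gm$a1)),
           loci(gm))
  for (p in unique(pop)) {
    out <- c(out, "Pop")
    for (i in which(pop == p)) {
      codes <- vapply(seq_len(ncol(gm$a1)), function(j) {
        enc <- function(v) {
          if (is.na(v)) return(fmt(0L))
          if (v == 0L) return(fmt(null_code))
          fmt(code_map$code[code_map$locus == loci(gm)[j] & code_map$allele == v])
        }
        paste0(enc(gm$a1[i, j]), enc(gm$a2[i, j]))
      }, character(1))
      out <- c(out, paste(individuals(gm)[i], ",", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  utils::write.table(code_map, paste0(path, ".alleles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

.read_structure_gm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop(path, ": empty file", call. = FALSE)
  locus_names <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2 != 0) {
    stop(path, ": STRUCTURE file must have two rows per individual", call. = FALSE)
  }
  n <- length(body) / 2L
  if (n == 0) {
    a <- matrix(integer(), 0, length(locus_names),
                dimnames = list(character(), locus_names))
    return(geno_matrix(a, a))
  }
  first <- strsplit(trimws(body[1]), "\\s+")[[1]]
  has_pop <- length(first) == length(locus_names) + 2L
  ids <- character(n); pops <- if (has_pop) character(n) else NULL
  a1 <- a2 <- matrix(NA_integer_, n, length(locus_names))
  for (i in seq_len(n)) {
    for (r in 1:2) {
      ln_no <- 2 * (i - 1) + r + 1L
      fields <- strsplit(trimws(body[2 * (i - 1) + r]), "\\s+")[[1]]
      if (length(fields) != length(locus_names) + 1L + has_pop) {
        stop(sprintf("%s:%d: expected %d fields, found %d", path, ln_no,
                     length(locus_names) + 1L + has_pop, length(fields)),
             call. = FALSE)
      }
      if (r == 1) {
        ids[i] <- fields[1]
        if (has_pop) pops[i] <- fields[2]
      } else if (fields[1] != ids[i]) {
        stop(sprintf("%s:%d: row pair id mismatch ('%s' vs '%s')", path, ln_no,
                     ids[i], fields[1]), call. = FALSE)
      }
      vals <- suppressWarnings(as.integer(fields[(2L + has_pop):length(fields)]))
      if (anyNA(vals)) stop(sprintf("%s:%d: non-numeric allele", path, ln_no), call. = FALSE)
      vals[vals == -9L] <- NA_integer_
      vals[vals == 999L] <- 0L
      if (any(vals < 0, na.rm = TRUE)) {
        stop(sprintf("%s:%d: bad allele code", path, ln_no), call. = FALSE)
      }
      if (r == 1) a1[i, ] <- vals else a2[i, ] <- vals
    }
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, locus_names)
  geno_matrix(a1, a2, pop = pops)
}

.write_structure_gm <- function(gm, path) {
  if (any(gm$a1 < 0, na.rm = TRUE)) stop("unencodable negative allele code", call. = FALSE)
  has_pop <- !is.null(gm$pop)
  enc <- function(v) ifelse(is.na(v), -9L, ifelse(v == 0L, 999L, v))
  out <- paste(loci(gm), collapse = " ")
  for (i in seq_len(nrow(gm$a1))) {
    pre <- c(individuals(gm)[i], if (has_pop) gsub("\\s", "_", unname(gm$pop[i])))
    out <- c(out,
             paste(c(pre, enc(gm$a1[i, ])), collapse = " "),
             paste(c(pre, enc(gm$a2[i, ])), collapse = " "))
  }
  writeLines(out, path)
}

#' Read a genetic linkage map
#'
#' @param path TSV with header columns `marker`, `linkage_group`, `cM`.
#' @return A tibble with one row per mapped marker.
#' @export
read_linkage_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("marker", "linkage_group", "cm")
  if (!all(need %in% names(df))) {
    stop("linkage map needs columns marker, linkage_group, cM", call. = FALSE)
  }
  out <- tibble::tibble(marker = as.character(df$marker),
                        linkage_group = as.character(df$linkage_group),
                        cM = as.numeric(df$cm))
  if (anyDuplicated(out$marker)) stop("mapped markers must be unique", call. = FALSE)
  if (any(out$cM < 0)) stop("cM positions must be >= 0", call. = FALSE)
  out
}

#' Read a marker scaffold-coordinate table
#'
#' @param path TSV with header columns `marker`, `scaffold`, `bp`.
#' @return A tibble.
#' @export
read_scaffolds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("marker", "scaffold", "bp") %in% names(df))) {
    stop("scaffold table needs columns marker, scaffold, bp", call. = FALSE)
  }
  tibble::tibble(marker = as.character(df$marker),
                 scaffold = as.character(df$scaffold),
                 bp = as.numeric(df$bp))
}
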