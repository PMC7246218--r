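#' File dialect description for genotype and clustering-result files
#'
#' @param format one of `"genepop"`, `"structure_input"`, `"structure_results"`.
#' @param allele_digits width of one allele code in a GenePop token (2 or 3).
#' @param missing_code integer allele code that marks a missing allele
#'   (default 0; STRUCTURE input uses -9 internally regardless).
#' @param rows_per_individual 1 or 2, structure_input only.
#' @return a `file_dialect` list.
#' @export
file_dialect <- function(format = c("genepop", "structure_input", "structure_results"),
                         allele_digits = 3L, missing_code = 0L,
                         rows_per_individual = 1L) {
  format <- match.arg(format)
  allele_digits <- as.integer(allele_digits)
  if (!allele_digits %in% c(2L, 3L)) stop("allele_digits must be 2 or 3")
  if (missing_code < 0) stop("missing_code must be >= 0")
  if (!rows_per_individual %in% c(1L, 2L)) stop("rows_per_individual must be 1 or 2")
  structure(list(format = format, allele_digits = allele_digits,
                 missing_code = as.integer(missing_code),
                 rows_per_individual = as.integer(rows_per_individual)),
            class = "file_dialect")
}

#' Read a GenePop-format genotype file
#'
#' Supports 2- and 3-digit allele dialects; a token whose first or second
#' half equals the dialect's missing code marks the whole genotype missing.
#'
#' @param path path to a GenePop text file.
#' @param dialect a [file_dialect()]; only `allele_digits` and `missing_code`
#'   are used.
#' @return a [genotype_matrix()]; population labels are `pop1`, `pop2`, ...
#'   in order of the file's `Pop` blocks.
#' @export
read_genepop <- function(path, dialect = file_dialect("genepop")) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GenePop parse error: file too short")
  w <- dialect$allele_digits
  # locus names: lines 2..(first "Pop"), one per line or comma-separated
  pop_lines <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_lines)) stop("GenePop parse error: no 'Pop' line found")
  first_pop <- pop_lines[1]
  if (first_pop < 3) stop("GenePop parse error at line ", first_pop,
                          ": 'Pop' before any locus names")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  loci <- unlist(strsplit(locus_lines[locus_lines != ""], ","))
  loci <- trimws(loci)
  if (any(loci == "")) stop("GenePop parse error: empty locus name in header")
  L <- length(loci)

  ids <- character(); pops <- character()
  a1 <- list(); a2 <- list()
  pop_idx <- 0L
  i <- first_pop
  n_in_block <- 0L
  while (i <= length(lines)) {
    line <- lines[i]
    if (toupper(trimws(line)) == "POP") {
      if (pop_idx > 0L && n_in_block == 0L)
        stop("GenePop validation error: empty Pop block before line ", i)
      pop_idx <- pop_idx + 1L
      n_in_block <- 0L
      i <- i + 1L
      next
    }
    if (trimws(line) == "") { i <- i + 1L; next }
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("GenePop parse error at line ", i, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) != L)
      stop("GenePop parse error at line ", i, ": ", length(toks),
           " genotype tokens for ", L, " loci (ragged row)")
    if (!all(grepl("^[0-9]+$", toks)))
      stop("GenePop parse error at line ", i, ": non-numeric genotype token")
    if (!all(nchar(toks) == 2L * w))
      stop("GenePop parse error at line ", i, ": token width inconsistent with allele_digits=", w)
    v1 <- as.integer(substr(toks, 1L, w))
    v2 <- as.integer(substr(toks, w + 1L, 2L * w))
    miss <- v1 == dialect$missing_code | v2 == dialect$missing_code
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop", pop_idx))
    a1[[length(a1) + 1L]] <- v1
    a2[[length(a2) + 1L]] <- v2
    n_in_block <- n_in_block + 1L
    i <- i + 1L
  }
  if (n_in_block == 0L)
    stop("GenePop validation error: empty final Pop block")
  genotype_matrix(do.call(rbind, a1), do.call(rbind, a2),
                  pop = pops, loci = loci, ids = make.unique(ids))
}

#' Write a genotype matrix as a GenePop file
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @param dialect a [file_dialect()]
#' @param title first (comment) line of the file
#' @return `path`, invisibly
#' @export
write_genepop <- function(g, path, dialect = file_dialect("genepop"),
                          title = "msatclust export") {
  w <- dialect$allele_digits
  maxcode <- max(c(g$allele1, g$allele2, dialect$missing_code), na.rm = TRUE)
  if (maxcode > 10^w - 1)
    stop("encoding error: allele code ", maxcode,
         " does not fit in ", w, " digits")
  fmt <- paste0("%0", w, "d")
  enc <- function(v) {
    out <- sprintf(fmt, ifelse(is.na(v), dialect$missing_code, v))
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in levels(g$pop)) {
    writeLines("Pop", con)
    rows <- which(g$pop == p)
    for (i in rows) {
      toks <- paste0(enc(g$allele1[i, ]), enc(g$allele2[i, ]))
      writeLines(paste0(g$ids[i], " , ", paste(toks, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a STRUCTURE input file
#'
#' One row per individual (or two, one per allele copy), a label column, a
#' population column coded as integers, then the allele codes; missing data
#' written as -9.
#'
#' @inheritParams write_genepop
#' @return `path`, invisibly
#' @export
write_structure_input <- function(g, path,
                                  dialect = file_dialect("structure_input")) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("id", "pop", g$loci), collapse = "\t"), con)
  popcode <- as.integer(g$pop)
  na9 <- function(v) ifelse(is.na(v), -9L, v)
  if (dialect$rows_per_individual == 1L) {
    for (i in seq_len(n_ind(g))) {
      geno <- as.vector(rbind(na9(g$allele1[i, ]), na9(g$allele2[i, ])))
      writeLines(paste(c(g$ids[i], popcode[i], geno), collapse = "\t"), con)
    }
  } else {
    for (i in seq_len(n_ind(g))) {
      writeLines(paste(c(g$ids[i], popcode[i], na9(g$allele1[i, ])), collapse = "\t"), con)
      writeLines(paste(c(g$ids[i], popcode[i], na9(g$allele2[i, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write one clustering replicate in the structure_results dialect
#'
#' A minimal STRUCTURE-results-like text file carrying the declared K, the
#' estimated ln probability of the data and the per-individual membership
#' (Q) table; [parse_structure_results()] reads it back.
#'
#' @param run a `replicate_run` (see [run_replicate()])
#' @param path output path
#' @param ids optional individual identifiers
#' @return `path`, invisibly
#' @export
write_structure_results <- function(run, path, ids = NULL) {
  q <- run$q
  if (is.null(ids)) ids <- rownames(q)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(q)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("msatclust clustering replicate (structure_results dialect)", con)
  writeLines(sprintf("K = %d", run$k), con)
  writeLines(sprintf("Estimated Ln Prob of Data = %.6f", run$ln_p_of_k), con)
  writeLines("Inferred ancestry of individuals:", con)
  for (i in seq_len(nrow(q))) {
    writeLines(paste0(sprintf("%d %s (0) 1 : ", i, ids[i]),
                      paste(sprintf("%.6f", q[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

parse_one_structure_result <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kline <- grep("^\\s*K\\s*=\\s*[0-9]+", lines, value = TRUE)
  if (!length(kline)) stop("parse error in ", path, ": no 'K = <int>' line")
  k <- as.integer(sub(".*K\\s*=\\s*([0-9]+).*", "\\1", kline[1]))
  lnline <- grep("Estimated Ln Prob of Data", lines, value = TRUE)
  if (!length(lnline))
    stop("parse error in ", path, ": missing 'Estimated Ln Prob of Data' line")
  lnp <- as.numeric(sub(".*[=:]\\s*(-?[0-9.eE+-]+)\\s*$", "\\1", lnline[1]))
  if (is.na(lnp)) stop("parse error in ", path, ": unreadable ln probability")
  anc <- grep("Inferred ancestry", lines)
  if (!length(anc)) stop("parse error in ", path, ": no ancestry table")
  body <- lines[(anc[1] + 1L):length(lines)]
  body <- body[trimws(body) != ""]
  qrows <- list(); pending <- numeric(0)
  for (line in body) {
    if (grepl(":", line, fixed = TRUE)) {
      if (length(pending)) { qrows[[length(qrows) + 1L]] <- pending }
      tail_part <- sub("^.*:", "", line)
      pending <- suppressWarnings(as.numeric(strsplit(trimws(tail_part), "[[:space:]]+")[[1]]))
    } else {
      # continuation of a wrapped Q row
      more <- suppressWarnings(as.numeric(strsplit(trimws(line), "[[:space:]]+")[[1]]))
      pending <- c(pending, more)
    }
  }
  if (length(pending)) qrows[[length(qrows) + 1L]] <- pending
  if (!length(qrows)) stop("parse error in ", path, ": empty Q table")
  widths <- lengths(qrows)
  if (any(widths != widths[1]) || anyNA(unlist(qrows)))
    stop("parse error in ", path, ": ragged or non-numeric Q table")
  q <- do.call(rbind, qrows)
  if (ncol(q) != k)
    stop("validation error in ", path, ": Q width ", ncol(q),
         " inconsistent with declared K=", k)
  rs <- rowSums(q)
  if (any(rs <= 0)) stop("validation error in ", path, ": non-positive Q row sum")
  q <- q / rs
  replicate_run(k = k, ln_p_of_k = lnp, q = q)
}

#' Parse external clustering replicates into a K-scan
#'
#' Each file is one replicate's results text in the structure_results
#' dialect; replicates are grouped by their declared K.  Q rows are
#' renormalized to sum to one.
#'
#' @param paths character vector of file paths
#' @return a `kscan` object (see [run_kscan()])
#' @export
parse_structure_results <- function(paths) {
  runs <- lapply(paths, parse_one_structure_result)
  ks <- vapply(runs, function(r) r$k, integer(1))
  grid <- sort(unique(ks))
  by_k <- lapply(grid, function(k) runs[ks == k])
  names(by_k) <- as.character(grid)
  new_kscan(grid, by_k)
}
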