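#' Construct a genotype matrix
#'
#' The package's genotype container: an animals-by-SNPs integer matrix of
#' A1-allele counts (2 = homozygous A1, 1 = heterozygous, 0 = homozygous
#' A2, `NA` = missing) together with the SNP map. By convention A1 is
#' intended to be the minor allele (see [orient_minor()]), so the call
#' codes double as minor-allele dosages. Chromosome labels are kept as
#' strings ("1"-"26", "X") to avoid lossy integer coercion; positions are
#' 1-based as in .bim/.map convention.
#'
#' @param calls Integer matrix, animals x SNPs, values in \{0, 1, 2, NA\}.
#' @param animal_ids,snp_ids Row / column identifiers.
#' @param chrom Character vector of per-SNP chromosome labels.
#' @param pos_bp Integer vector of per-SNP 1-based coordinates.
#' @param a1,a2 Per-SNP allele characters; counted allele is A1.
#' @param multiallelic Logical per-SNP flag: more than two alleles were
#'   observed at read time (calls are set missing; QC removes the SNP).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, animal_ids, snp_ids, chrom, pos_bp,
                            a1, a2, multiallelic = NULL) {
  n <- length(animal_ids)
  m <- length(snp_ids)
  stopifnot(is.matrix(calls), nrow(calls) == n, ncol(calls) == m,
            length(chrom) == m, length(pos_bp) == m,
            length(a1) == m, length(a2) == m)
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, m)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(animal_ids, snp_ids)
  structure(list(calls = calls,
                 animal_ids = as.character(animal_ids),
                 snp_ids = as.character(snp_ids),
                 chrom = as.character(chrom),
                 pos_bp = as.integer(pos_bp),
                 a1 = as.character(a1), a2 = as.character(a2),
                 multiallelic = as.logical(multiallelic)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$animal_ids), "animals x",
      length(x$snp_ids), "SNPs on", length(unique(x$chrom)),
      "chromosome(s);", sum(x$multiallelic), "flagged multi-allelic;",
      sprintf("%.2f%%", 100 * mean(is.na(x$calls))), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Re-orient genotype calls so A1 is the minor allele
#'
#' Recomputes allele frequencies from the observed calls and swaps A1/A2
#' (flipping calls g -> 2 - g) wherever A1 is currently the major allele.
#' At frequency exactly 0.5 the alphabetically first allele is taken as A1.
#' Orientation is data-derived because chip-manifest orientation is not
#' part of the file formats this package reads.
#'
#' @param G A `genotype_matrix`.
#' @return The re-oriented `genotype_matrix`.
#' @export
orient_minor <- function(G) {
  f1 <- colMeans(G$calls, na.rm = TRUE) / 2  # frequency of A1
  f1[is.nan(f1)] <- 0
  flip <- f1 > 0.5 | (f1 == 0.5 & G$a2 < G$a1)
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    G$calls[, flip] <- 2L - G$calls[, flip]
    tmp <- G$a1[flip]
    G$a1[flip] <- G$a2[flip]
    G$a2[flip] <- tmp
  }
  G
}

#' Read PLINK text genotypes (.ped / .map)
#'
#' The .map file has 4 whitespace-separated columns (chromosome, SNP id,
#' genetic distance, bp position); the .ped has 6 leading columns (family,
#' individual, father, mother, sex, phenotype) followed by two allele
#' columns per SNP. The allele pair "0 0" codes a missing call. A1 is the
#' minor allele determined from observed frequencies (ties broken
#' alphabetically). SNPs at which more than two distinct alleles are
#' observed are flagged multi-allelic, their calls set missing, and left
#' for QC to remove.
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @return A `genotype_matrix` with A1 = minor allele.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, colClasses = "character")
  if (ncol(map) != 4L) {
    stop("format error: .map must have 4 columns, found ", ncol(map),
         call. = FALSE)
  }
  m <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("format error: ragged .ped row ", which(lens != want)[1L],
         " (", lens[lens != want][1L], " fields, expected ", want, ")",
         call. = FALSE)
  }
  n <- length(toks)
  ids <- vapply(toks, `[[`, "", 2L)
  allele <- matrix("", nrow = n, ncol = 2L * m)
  for (i in seq_len(n)) allele[i, ] <- toks[[i]][-(1:6)]
  al1 <- allele[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  al2 <- allele[, seq(2L, 2L * m, by = 2L), drop = FALSE]

  calls <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  multi <- logical(m)
  for (j in seq_len(m)) {
    x1 <- al1[, j]
    x2 <- al2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      multi[j] <- TRUE
      a1[j] <- alleles[1L]
      a2[j] <- alleles[2L]
      next  # calls stay missing; QC removes the SNP
    }
    if (length(alleles) == 0L) {
      a1[j] <- "0"
      a2[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      # monomorphic: the observed allele is the major (A2); A1 unknown
      a1[j] <- "0"
      a2[j] <- alleles[1L]
      g <- rep(0L, n)
      g[miss] <- NA_integer_
      calls[, j] <- g
      next
    }
    counts <- table(factor(obs, levels = alleles))
    # minor first; alphabetical tie-break comes free from sort() above
    ord <- order(counts)
    a1[j] <- alleles[ord[1L]]
    a2[j] <- if (length(alleles) == 2L) alleles[ord[length(ord)]] else "0"
    g <- (x1 == a1[j]) + (x2 == a1[j])
    g[miss] <- NA_integer_
    calls[, j] <- g
  }
  genotype_matrix(calls, ids, map[[2L]], map[[1L]],
                  as.integer(map[[4L]]), a1, a2, multi)
}

# PLINK-1 .bed dialect: magic 0x6C 0x1B, mode 0x01 (SNP-major); 2 bits per
# genotype, first sample in the low-order bits of each byte;
# 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2.
BED_MAGIC <- as.raw(c(0x6C, 0x1B))

# bed 2-bit code -> A1 count (index raw code + 1)
BED_DECODE <- c(2L, NA_integer_, 1L, 0L)

#' Read / write PLINK binary genotypes (.bed / .bim / .fam)
#'
#' Only the SNP-major layout (mode byte 0x01) is supported; the obsolete
#' individual-major mode raises an unsupported-mode error. A1/A2 are taken
#' from the .bim as authoritative, so `read_plink_binary()` after
#' [write_plink_binary()] reproduces the matrix exactly, including
#' orientation.
#'
#' @param bed_path,bim_path,fam_path Paths to the PLINK trio.
#' @return A `genotype_matrix`.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  bim <- utils::read.table(bim_path, colClasses = "character")
  if (ncol(bim) != 6L) {
    stop("format error: .bim must have 6 columns", call. = FALSE)
  }
  fam <- utils::read.table(fam_path, colClasses = "character")
  if (ncol(fam) < 2L) {
    stop("format error: .fam must have at least 2 columns", call. = FALSE)
  }
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- (n + 3L) %/% 4L
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC)) {
    stop("format error: bad .bed magic bytes", call. = FALSE)
  }
  if (raw[3L] == as.raw(0x00)) {
    stop("unsupported-mode error: individual-major .bed (mode 0x00)",
         call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("format error: unknown .bed mode byte", call. = FALSE)
  }
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    stop("truncation error: .bed has ", length(body),
         " data bytes, expected ", bytes_per_snp * m, call. = FALSE)
  }
  # unpack all 2-bit codes at once: 4 codes per byte, low bits first
  v <- as.integer(body)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  codes <- matrix(codes, nrow = 4L * bytes_per_snp, ncol = m)
  calls <- matrix(BED_DECODE[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  genotype_matrix(calls, fam[[2L]], bim[[2L]], bim[[1L]],
                  as.integer(bim[[4L]]), bim[[5L]], bim[[6L]])
}

#' @rdname read_plink_binary
#' @param G A `genotype_matrix` to serialize.
#' @param prefix Output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return Invisibly, the three file paths.
#' @export
write_plink_binary <- function(G, prefix) {
  n <- length(G$animal_ids)
  m <- length(G$snp_ids)
  bim <- data.frame(G$chrom, G$snp_ids, 0L, G$pos_bp, G$a1, G$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$animal_ids, G$animal_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # A1 count -> bed code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  enc <- matrix(0L, n, m)
  enc[G$calls == 1L] <- 2L
  enc[G$calls == 0L] <- 3L
  enc[is.na(G$calls)] <- 1L
  bytes_per_snp <- (n + 3L) %/% 4L
  padded <- matrix(0L, 4L * bytes_per_snp, m)
  padded[seq_len(n), ] <- enc
  i4 <- seq(1L, 4L * bytes_per_snp, by = 4L)
  bytes <- padded[i4, , drop = FALSE] +
    4L * padded[i4 + 1L, , drop = FALSE] +
    16L * padded[i4 + 2L, , drop = FALSE] +
    64L * padded[i4 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, as.raw(0x01), as.raw(as.vector(bytes))), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
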