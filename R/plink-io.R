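#' Read PLINK-format genotypes
#'
#' Reads a diploid SNP panel from PLINK text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`, SNP-major) files. Calls count copies of the A1
#' allele: for binary input A1 is the fifth `.bim` column; for text input the
#' counted allele is taken from an `<prefix>.a1` sidecar (two columns: marker
#' id, allele — the format of PLINK's `--a1-allele` file) when present, and
#' otherwise defaults to the minor allele with a lexicographic tie-break.
#'
#' Non-numeric or out-of-range chromosome codes are retained with `chrom = 0`
#' and removed later by [apply_snp_qc()]; the same holds for unmapped markers
#' (`pos_bp <= 0`).
#'
#' @param prefix path prefix of the fileset (without extension)
#' @param format `"text"` or `"binary"`
#' @param pop_table optional path to a two-column TSV (sample_id, population);
#'   when absent, the family ID column provides the population label.
#' @return a [genotype_dataset()]
#' @export
read_plink <- function(prefix, format = c("binary", "text"), pop_table = NULL) {
  format <- match.arg(format)
  if (format == "text") {
    ds <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"),
                          a1_file = paste0(prefix, ".a1"))
  } else {
    ds <- read_plink_bed(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                         paste0(prefix, ".fam"))
  }
  if (!is.null(pop_table)) {
    pt <- utils::read.table(pop_table, header = FALSE, sep = "\t",
                            col.names = c("sample_id", "population"),
                            stringsAsFactors = FALSE)
    idx <- match(ds$samples$sample_id, pt$sample_id)
    if (anyNA(idx))
      stop("pop_table is missing samples: ",
           paste(ds$samples$sample_id[is.na(idx)], collapse = ", "))
    ds$samples$population <- pt$population[idx]
    rownames(ds$calls) <- ds$samples$sample_id
  }
  ds
}

read_map <- function(map_path) {
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(map) == 0) stop("empty marker file: ", map_path)
  if (ncol(map) < 4) stop("map file needs 4 columns (chrom id cM pos)")
  chrom <- suppressWarnings(as.integer(map[[1]]))
  chrom[is.na(chrom)] <- 0L   # non-numeric codes (X, Y, MT, ...): QC fodder
  data.frame(id = as.character(map[[2]]), chrom = chrom,
             pos_bp = as.integer(map[[4]]), stringsAsFactors = FALSE)
}

read_plink_text <- function(ped_path, map_path, a1_file = NULL) {
  map <- read_map(map_path)
  L <- nrow(map)
  if (anyDuplicated(map$id)) stop("duplicate marker ids in ", map_path)
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty ped file: ", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(toks)
  if (any(nfield != 6 + 2 * L))
    stop(sprintf("ped/map dimension mismatch: expected %d fields, found %d",
                 6 + 2 * L, nfield[which(nfield != 6 + 2 * L)[1]]))
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  samples <- data.frame(sample_id = tok[, 2], population = tok[, 1],
                        sex = suppressWarnings(as.integer(tok[, 5])),
                        stringsAsFactors = FALSE)
  al1 <- tok[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  al2 <- tok[, 6 + 2 * seq_len(L), drop = FALSE]
  a1_fixed <- NULL
  if (!is.null(a1_file) && file.exists(a1_file)) {
    a1t <- utils::read.table(a1_file, header = FALSE, stringsAsFactors = FALSE)
    a1_fixed <- stats::setNames(as.character(a1t[[2]]), as.character(a1t[[1]]))
  }
  calls <- matrix(NA_integer_, nrow(tok), L)
  a1 <- a2 <- character(L)
  for (l in seq_len(L)) {
    x1 <- al1[, l]; x2 <- al2[, l]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    if (length(obs) == 0) {
      a1[l] <- "0"; a2[l] <- "0"
      next
    }
    tab <- sort(table(obs))      # ascending count; names sorted on ties
    alleles <- names(tab)
    if (length(alleles) > 2)
      stop("marker ", map$id[l], " has >2 alleles in ", ped_path)
    if (!is.null(a1_fixed) && !is.na(a1_fixed[map$id[l]])) {
      a1[l] <- unname(a1_fixed[map$id[l]])
      a2[l] <- if (length(alleles) == 2) setdiff(alleles, a1[l]) else
        if (alleles[1] == a1[l]) "0" else alleles[1]
    } else {
      a1[l] <- alleles[1]        # minor (or lexicographically first on tie)
      a2[l] <- if (length(alleles) == 2) alleles[2] else "0"
    }
    g <- (x1 == a1[l]) + (x2 == a1[l])
    g[miss] <- NA_integer_
    calls[, l] <- g
  }
  map$a1 <- a1; map$a2 <- a2
  genotype_dataset(map, samples, calls)
}

read_plink_bed <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(bim) == 0) stop("empty marker file: ", bim_path)
  chrom <- suppressWarnings(as.integer(bim[[1]]))
  chrom[is.na(chrom)] <- 0L
  markers <- data.frame(id = as.character(bim[[2]]), chrom = chrom,
                        pos_bp = as.integer(bim[[4]]),
                        a1 = as.character(bim[[5]]), a2 = as.character(bim[[6]]),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(markers$id)) stop("duplicate marker ids in ", bim_path)
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(fam[[2]]),
                        population = as.character(fam[[1]]),
                        sex = suppressWarnings(as.integer(fam[[5]])),
                        stringsAsFactors = FALSE)
  n <- nrow(samples); L <- nrow(markers)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpl <- ceiling(n / 4)
  if (length(raw) - 3 != bpl * L)
    stop(sprintf(".bed size mismatch: expected %d data bytes, found %d",
                 bpl * L, length(raw) - 3))
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample-fastest within byte
  codes <- matrix(0L, 4 * bpl, L)
  m <- matrix(body, bpl, L)
  codes[seq(1, 4 * bpl, by = 4), ] <- m %% 4L
  codes[seq(2, 4 * bpl, by = 4), ] <- (m %/% 4L) %% 4L
  codes[seq(3, 4 * bpl, by = 4), ] <- (m %/% 16L) %% 4L
  codes[seq(4, 4 * bpl, by = 4), ] <- (m %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 = hom A1 (2 copies), 10 = het, 11 = hom A2, 01 = missing
  calls <- matrix(NA_integer_, n, L)
  calls[codes == 0L] <- 2L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 0L
  genotype_dataset(markers, samples, calls)
}

#' Write PLINK-format genotypes
#'
#' Writers are deterministic byte-for-byte for a given dataset. In text mode
#' an `<prefix>.a1` sidecar recording each marker's counted allele is written
#' alongside `.ped`/`.map` (the format of PLINK's `--a1-allele` file), so that
#' reading the fileset back restores the exact 0/1/2 coding even where A1 is
#' not the minor allele.
#'
#' @param ds a [genotype_dataset()]
#' @param prefix output path prefix
#' @param format `"binary"` or `"text"`
#' @return `prefix`, invisibly
#' @export
write_plink <- function(ds, prefix, format = c("binary", "text")) {
  format <- match.arg(format)
  m <- ds$markers; s <- ds$samples
  if (format == "text") {
    utils::write.table(data.frame(m$chrom, m$id, 0, m$pos_bp),
                       paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(m$id, m$a1), paste0(prefix, ".a1"),
                       quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    g <- ds$calls
    n <- nrow(g); L <- ncol(g)
    geno_txt <- matrix("0 0", n, L)
    for (l in seq_len(L)) {
      col <- g[, l]
      geno_txt[!is.na(col) & col == 2L, l] <- paste(m$a1[l], m$a1[l])
      geno_txt[!is.na(col) & col == 1L, l] <- paste(m$a1[l], m$a2[l])
      geno_txt[!is.na(col) & col == 0L, l] <- paste(m$a2[l], m$a2[l])
    }
    lines <- paste(s$population, s$sample_id, 0, 0, s$sex, -9,
                   apply(geno_txt, 1, paste, collapse = " "))
    writeLines(lines, paste0(prefix, ".ped"))
  } else {
    utils::write.table(data.frame(m$chrom, m$id, 0, m$pos_bp, m$a1, m$a2),
                       paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(s$population, s$sample_id, 0, 0, s$sex, -9),
                       paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    g <- ds$calls
    n <- nrow(g); L <- ncol(g)
    code <- matrix(1L, n, L)            # 01 = missing
    code[!is.na(g) & g == 2L] <- 0L
    code[!is.na(g) & g == 1L] <- 2L
    code[!is.na(g) & g == 0L] <- 3L
    bpl <- ceiling(n / 4)
    pad <- matrix(0L, 4 * bpl - n, L)   # padding bits are zero
    cd <- rbind(code, pad)
    i1 <- seq(1, 4 * bpl, by = 4)
    bytes <- cd[i1, , drop = FALSE] + 4L * cd[i1 + 1, , drop = FALSE] +
      16L * cd[i1 + 2, , drop = FALSE] + 64L * cd[i1 + 3, , drop = FALSE]
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(bytes)), con)
  }
  invisible(prefix)
}

#' Write the sample-to-population table
#' @param ds a [genotype_dataset()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_pop_table <- function(ds, path) {
  utils::write.table(ds$samples[, c("sample_id", "population")], path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
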