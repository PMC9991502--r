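#' Read a genotype table
#'
#' Reads a samples x markers dosage table either from a delimited text file
#' (tab or comma, sniffed; header row mandatory; first column = sample id;
#' remaining columns = marker dosages in \{0, 1, 2\}, fractional values in
#' [0, 2] allowed for imputed panels, \code{NA} for missing) or from a PLINK
#' bed/bim/fam triple (\code{path} is the prefix without extension).
#'
#' @param path file path (delimited) or PLINK prefix.
#' @param format \code{"delimited"} or \code{"plink"}.
#' @param mapPath optional delimited marker map with columns
#'   \code{marker, chrom, pos} (delimited format only; PLINK carries its own
#'   map in the .bim file). Without a map, markers are placed on chromosome
#'   "1" at positions \code{1..p}.
#' @return a \linkS4class{GenotypeMatrix}; sample order is preserved.
#' @export
readGenotypeTable <- function(path, format = c("delimited", "plink"),
                              mapPath = NULL) {
  format <- match.arg(format)
  if (format == "plink") return(readPlink(path))
  stopIfNot(file.exists(path), "file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE, na.strings = "NA"),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  stopIfNot(ncol(dt) >= 2, "genotype table needs a sample-id column plus markers: ", path)
  ids <- as.character(dt[[1]])
  d <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(d))
    stop("non-numeric dosage in '", path, "' (first bad marker column: ",
         colnames(d)[which(!apply(d, 2, is.numeric))[1]], ")", call. = FALSE)
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop("dosage outside [0, 2] at record ", bad[1, 1], " (sample ", ids[bad[1, 1]],
         "), marker ", colnames(d)[bad[1, 2]], call. = FALSE)
  chrom <- NULL; pos <- NULL
  if (!is.null(mapPath)) {
    mp <- readMarkerMap(mapPath)
    mp <- mp[match(colnames(d), mp$marker), , drop = FALSE]
    stopIfNot(!anyNA(mp$marker), "map does not cover all markers in ", path)
    chrom <- mp$chrom; pos <- mp$pos
  }
  GenotypeMatrix(d, chrom = chrom, pos = pos, sampleIds = ids)
}

#' Write a genotype table
#'
#' Inverse of [readGenotypeTable()]. Delimited output is tab-separated with a
#' mandatory header; missing dosages serialize as \code{"NA"}; the marker map
#' is written alongside when \code{mapPath} is given. PLINK output writes the
#' bed/bim/fam triple at prefix \code{path} (dosages are rounded to
#' \{0, 1, 2\}; fractional dosages are not representable in .bed).
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @inheritParams readGenotypeTable
#' @return invisibly, the main path written.
#' @export
writeGenotypeTable <- function(G, path, format = c("delimited", "plink"),
                               mapPath = NULL) {
  format <- match.arg(format)
  if (format == "plink") return(writePlink(G, path))
  d <- dosages(G)
  d[missingMask(G)] <- NA
  out <- data.frame(sample = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(mapPath))
    data.table::fwrite(markerMap(G), mapPath, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a marker map (marker, chrom, pos)
#'
#' @param path delimited file with header columns \code{marker},
#'   \code{chrom}, \code{pos} (1-based bp).
#' @return data.frame
#' @export
readMarkerMap <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  mp <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopIfNot(all(c("marker", "chrom", "pos") %in% names(mp)),
            "marker map needs columns marker, chrom, pos: ", path)
  data.frame(marker = as.character(mp$marker), chrom = as.character(mp$chrom),
             pos = as.integer(mp$pos), stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' Delimited samples x traits table; first column sample id, remaining
#' columns numeric trait values with \code{NA} for missing.
#'
#' @param path file path.
#' @param focal focal trait id or column index (default: first trait).
#' @return a \linkS4class{PhenotypeBlock}
#' @export
readPhenotypeTable <- function(path, focal = 1L) {
  stopIfNot(file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE, na.strings = "NA")
  stopIfNot(ncol(dt) >= 2, "phenotype table needs a sample-id column plus traits: ", path)
  v <- as.matrix(dt[, -1, drop = FALSE])
  PhenotypeBlock(v, focalIndex = focal, sampleIds = as.character(dt[[1]]))
}

#' Read a gene annotation table
#'
#' Four columns: \code{gene}, \code{chrom}, \code{start}, \code{end}
#' (1-based, inclusive).
#'
#' @param path delimited file with header.
#' @return data.frame with the four columns, \code{start <= end} enforced.
#' @export
readGeneTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  g <- data.table::fread(path, header = TRUE, data.table = FALSE)
  stopIfNot(all(c("gene", "chrom", "start", "end") %in% names(g)),
            "gene table needs columns gene, chrom, start, end: ", path)
  g <- data.frame(gene = as.character(g$gene), chrom = as.character(g$chrom),
                  start = as.integer(g$start), end = as.integer(g$end),
                  stringsAsFactors = FALSE)
  stopIfNot(all(g$start <= g$end), "gene intervals must have start <= end")
  g
}

# --- PLINK bed/bim/fam (SNP-major v1.00 .bed) ------------------------------
# 2-bit codes per sample, LSB-first within each byte:
#   00 -> 2 copies of allele A1, 10 -> 1 copy, 11 -> 0 copies, 01 -> missing.

readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    stopIfNot(file.exists(f), "PLINK triple incomplete, missing: ", f)
  fm <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bm <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fm); p <- nrow(bm)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * p)
  stopIfNot(length(raw) >= 3 && raw[1] == as.raw(0x6c) && raw[2] == as.raw(0x1b),
            "not a PLINK .bed file (bad magic): ", bed)
  stopIfNot(raw[3] == as.raw(0x01), "only SNP-major .bed supported: ", bed)
  body <- as.integer(raw[-(1:3)])
  stopIfNot(length(body) == ceiling(n / 4) * p,
            "truncated .bed: expected ", ceiling(n / 4) * p, " body bytes in ", bed)
  # decode: lookup table byte -> 4 dosages
  codes <- c(2, NA, 1, 0)  # index by 2-bit value + 1
  lut <- matrix(0, nrow = 256, ncol = 4)
  b <- 0:255
  for (k in 1:4) {
    lut[, k] <- codes[bitwAnd(bitwShiftR(b, 2L * (k - 1L)), 3L) + 1L]
  }
  bpm <- ceiling(n / 4)
  d <- matrix(NA_real_, n, p)
  bytes <- matrix(body, nrow = bpm, ncol = p)
  for (k in 1:4) {
    idx <- seq.int(k, by = 4L, length.out = bpm)
    idx <- idx[idx <= n]
    if (!length(idx)) next
    d[idx, ] <- lut[bytes[seq_along(idx), , drop = FALSE] + 1L, k]
  }
  GenotypeMatrix(d, chrom = as.character(bm[[1]]), pos = as.integer(bm[[4]]),
                 markerIds = as.character(bm[[2]]),
                 sampleIds = as.character(fm[[2]]))
}

writePlink <- function(G, prefix) {
  d <- round(dosages(G))
  d[missingMask(G)] <- NA
  n <- nrow(d); p <- ncol(d)
  code <- matrix(1L, n, p)           # 01 = missing
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  bpm <- ceiling(n / 4)
  pad <- bpm * 4 - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, p))  # pad bits read as dosage 0, ignored
  shift <- 4L^(0:3)
  bytes <- integer(bpm * p)
  for (k in 1:4) {
    rows <- seq.int(k, by = 4L, length.out = bpm)
    bytes <- bytes + as.integer(code[rows, , drop = FALSE]) * shift[k]
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(bytes)), paste0(prefix, ".bed"))
  mp <- markerMap(G)
  utils::write.table(
    data.frame(mp$chrom, mp$marker, 0, mp$pos, "A", "B"),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ids <- sampleIds(G)
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Marker quality control
#'
#' Applies one of two marker QC rules. The \code{"wheat"} rule removes markers
#' with call rate <= 0.5 or minor allele frequency <= 0.05, then imputes
#' remaining missing dosages by the marker mean (mask cleared). The
#' \code{"arabidopsis"} rule removes markers with MAF <= 0.05 or missing rate
#' >= 0.1 and performs no imputation. MAF is \code{min(f, 1 - f)} with
#' \code{f = mean(dosage)/2} over observed cells. Both rules are idempotent.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param rule \code{"wheat"} or \code{"arabidopsis"}
#' @return the filtered \linkS4class{GenotypeMatrix}
#' @export
filterMarkers <- function(G, rule = c("wheat", "arabidopsis")) {
  rule <- match.arg(rule)
  maf <- markerMaf(G)
  maf[is.na(maf)] <- 0  # all-missing marker: treat as monomorphic, drop
  missRate <- colMeans(missingMask(G))
  if (rule == "wheat") {
    keep <- (1 - missRate) > 0.5 & maf > 0.05
  } else {
    keep <- missRate < 0.1 & maf > 0.05
  }
  if (!any(keep))
    stop("all markers removed by the '", rule, "' rule: empty marker panel",
         call. = FALSE)
  G2 <- G[, which(keep)]
  if (rule == "wheat" && any(G2@missingMask)) {
    d <- G2@dosages
    mu <- colMeans(d, na.rm = TRUE)
    miss <- which(G2@missingMask, arr.ind = TRUE)
    d[miss] <- mu[miss[, 2]]
    G2@dosages <- d
    G2@missingMask[] <- FALSE
  }
  validObject(G2)
  G2
}

#' Write / read a marker effect table
#'
#' Tab-delimited with header, deterministic column order
#' (\code{marker, chrom, pos, estimate, explainedVariance, proportion,
#' significant}, then any extras). \code{NaN} estimates serialize as
#' \code{"NA"}. Round-trips through [readEffectTable()].
#'
#' @param results data.frame containing at least \code{marker},
#'   \code{estimate}, \code{explainedVariance}, \code{significant}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEffectTable <- function(results, path) {
  need <- c("marker", "estimate", "explainedVariance", "significant")
  stopIfNot(all(need %in% names(results)),
            "results must contain columns: ", paste(need, collapse = ", "))
  lead <- intersect(c("marker", "chrom", "pos", "estimate",
                      "explainedVariance", "proportion", "significant"),
                    names(results))
  results <- results[, c(lead, setdiff(names(results), lead)), drop = FALSE]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], function(x) { x[is.nan(x)] <- NA; x })
  ok <- tryCatch({
    data.table::fwrite(results, path, sep = "\t", na = "NA", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  stopIfNot(ok, "cannot write effect table to: ", path)
  invisible(path)
}

#' @rdname writeEffectTable
#' @export
readEffectTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: ", path)
  data.table::fread(path, header = TRUE, data.table = FALSE, na.strings = "NA")
}
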