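#' Read and write the pipeline's on-disk formats
#'
#' Thin, round-trip-stable readers/writers: FASTA via Biostrings; BED and
#' bedGraph as 0-based half-open text; a minimal two-sample VCF subset
#' (CHROM, POS, REF, ALT, QUAL, the six hard-filter INFO keys, GT); and a
#' SAM-subset (QNAME, FLAG, RNAME, POS, CIGAR, SEQ plus `XS`/`XA` truth
#' tags) for the simulated aligned records. Malformed lines raise an error
#' naming the file, line number and offending text.
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "DNAStringSet"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

.badLine <- function(path, i, line, why) {
  stop(sprintf("%s:%d: %s: %s", path, i, why, line), call. = FALSE)
}

#' @rdname pipeline-io
#' @param bed data.frame with `chrom`, `start` (0-based), `end` (half-open)
#'   and optional further columns.
#' @export
writeBed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- data.frame(chrom = character(length(lines)),
                    start = integer(length(lines)),
                    end = integer(length(lines)))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) .badLine(path, i, lines[i], "expected >= 3 BED fields")
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || e <= s)
      .badLine(path, i, lines[i], "invalid BED interval")
    out$chrom[i] <- f[1]; out$start[i] <- s; out$end[i] <- e
  }
  out
}

#' @rdname pipeline-io
#' @param cpgTable per-CpG call table (`chrom`, `pos`, `meth`, `unmeth`).
#' @export
writeBedGraph <- function(cpgTable, path) {
  cov <- cpgTable$meth + cpgTable$unmeth
  x <- cpgTable[cov > 0, , drop = FALSE]
  bg <- data.frame(chrom = x$chrom, start = x$pos - 1L, end = x$pos,
                   level = round(x$meth / (x$meth + x$unmeth), 6))
  write.table(bg, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @param variants data.frame as accepted by [hardFilterVariants()].
#' @export
writeVcfSubset <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmother\tfather"),
    con)
  ann <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  fmtInfo <- function(i) {
    v <- unlist(variants[i, ann])
    paste(paste0(ann[!is.na(v)], "=", v[!is.na(v)]), collapse = ";")
  }
  gtCode <- function(gt, ref, alt) {
    a <- strsplit(gt, "[/|]")[[1]]
    paste(ifelse(a == ref, "0", "1"), collapse = "/")
  }
  for (i in seq_len(nrow(variants))) {
    writeLines(paste(
      variants$chrom[i], variants$pos[i], ".", variants$ref[i],
      variants$alt[i], ".", ".", fmtInfo(i), "GT",
      gtCode(variants$gtMaternal[i], variants$ref[i], variants$alt[i]),
      gtCode(variants$gtPaternal[i], variants$ref[i], variants$alt[i]),
      sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readVcfSubset <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  ann <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  n <- length(body)
  out <- data.frame(chrom = character(n), pos = integer(n),
                    ref = character(n), alt = character(n),
                    gtMaternal = character(n), gtPaternal = character(n))
  for (a in ann) out[[a]] <- NA_real_
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) .badLine(path, i, body[i], "expected 11 VCF fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) .badLine(path, i, body[i], "invalid POS")
    out$chrom[i] <- f[1]; out$pos[i] <- pos
    out$ref[i] <- f[4]; out$alt[i] <- f[5]
    for (kv in strsplit(f[8], ";", fixed = TRUE)[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2 && p[1] %in% ann)
        out[[p[1]]][i] <- as.numeric(p[2])
    }
    decode <- function(code) {
      al <- strsplit(code, "[/|]")[[1]]
      paste(ifelse(al == "0", f[4], f[5]), collapse = "/")
    }
    out$gtMaternal[i] <- decode(f[10])
    out$gtPaternal[i] <- decode(f[11])
  }
  out
}

#' @rdname pipeline-io
#' @param reads aligned-record data.frame (`qname`, `flag`, `chrom`,
#'   `pos`, `cigar`, `seq`, optional `strand`/`allele` truth tags).
#' @export
writeSamSubset <- function(reads, path) {
  tags <- character(nrow(reads))
  if ("strand" %in% names(reads))
    tags <- paste0(tags, "\tXS:Z:", reads$strand)
  if ("allele" %in% names(reads))
    tags <- paste0(tags, "\tXA:Z:", reads$allele)
  lines <- paste0(reads$qname, "\t", reads$flag, "\t", reads$chrom, "\t",
                  reads$pos, "\t255\t", reads$cigar, "\t*\t0\t0\t",
                  reads$seq, "\t*", tags)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readSamSubset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  n <- length(lines)
  out <- data.frame(qname = character(n), flag = integer(n),
                    chrom = character(n), pos = integer(n),
                    cigar = character(n), seq = character(n),
                    strand = NA_character_, allele = NA_character_)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) .badLine(path, i, lines[i], "expected >= 11 SAM fields")
    pos <- suppressWarnings(as.integer(f[4]))
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || is.na(flag)) .badLine(path, i, lines[i], "invalid POS/FLAG")
    out$qname[i] <- f[1]; out$flag[i] <- flag; out$chrom[i] <- f[3]
    out$pos[i] <- pos; out$cigar[i] <- f[6]; out$seq[i] <- f[10]
    if (length(f) > 11) for (tg in f[12:length(f)]) {
      if (startsWith(tg, "XS:Z:")) out$strand[i] <- substring(tg, 6)
      if (startsWith(tg, "XA:Z:")) out$allele[i] <- substring(tg, 6)
    }
  }
  if (all(is.na(out$strand))) out$strand <- NULL
  if (all(is.na(out$allele))) out$allele <- NULL
  out
}

#' @rdname pipeline-io
#' @param df any data.frame.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname pipeline-io
#' @param image numeric matrix 0..255.
#' @export
writeSlidePng <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readSlidePng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}
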