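# Readers/writers for the genomic text formats the pipeline touches.
# Internal convention everywhere: 0-based half-open intervals; VCF and
# RepeatMasker .out are 1-based on disk and converted at this boundary.

#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return a named character vector of uppercase chromosome sequences
#'   (alphabet A/C/G/T/N), in file order.
#' @export
read_fasta <- function(path) {
  # BStringSet first: DNAStringSet silently drops invalid letters
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("FASTA contains no records: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate chromosome name in FASTA: ",
                              nm[duplicated(nm)][1])
  out <- toupper(as.character(seqs))
  names(out) <- nm
  if (any(nchar(out) == 0L)) stop("empty FASTA record: ", nm[nchar(out) == 0L][1])
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) stop("non-nucleotide character in sequence: ", nm[bad][1])
  out
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(!is.null(names(genome)), all(nzchar(names(genome))))
  ss <- Biostrings::DNAStringSet(unname(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param path file path.
#' @return `read_bed` returns a data.frame with columns `chrom`, `start`,
#'   `end` and, when present, `name`, `score`, `strand`.
#' @rdname bed_io
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (!nrow(dt)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  nc <- ncol(dt)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(nc, 6L))]
  dt <- dt[, seq_along(cols), with = FALSE]
  data.table::setnames(dt, cols)
  out <- as.data.frame(dt)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  if (any(out$start >= out$end)) stop("BED interval with start >= end in ", path)
  out
}

#' @param intervals data.frame with at least `chrom`, `start`, `end`
#'   (optionally `name`, `score`, `strand`).
#' @rdname bed_io
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  stopifnot(all(c("chrom", "start", "end") %in% cols))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a numeric track as bedGraph
#'
#' Intervals must be non-overlapping; runs of equal value over adjacent
#' intervals are merged on output.
#'
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (!nrow(track)) { file.create(path); return(invisible(path)) }
  if (any(!is.finite(track$value))) stop("bedGraph track contains non-finite values")
  if (any(track$start >= track$end)) stop("track interval with start >= end")
  dt <- data.table::as.data.table(track)[order(chrom, start)]
  if (any(dt[, start < data.table::shift(end, fill = -1L), by = chrom]$V1))
    stop("overlapping intervals in bedGraph track")
  # merge adjacent runs of identical value
  dt[, run := cumsum(!(value == data.table::shift(value, fill = NA) &
                       start == data.table::shift(end, fill = -1L) &
                       chrom == data.table::shift(chrom, fill = "")))]
  merged <- dt[, .(start = start[1L], end = end[.N], value = value[1L]),
               by = .(chrom, run)][, run := NULL]
  data.table::fwrite(merged[, .(chrom, start, end, value)], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1))
  as.data.frame(dt)
}

te_classes <- c("LINE", "SINE", "LTR", "DNA", "Other")

# "LINE/L1" -> LINE; anything not in the four canonical classes -> Other
parse_te_class <- function(class_family) {
  cls <- sub("/.*$", "", class_family)
  fam <- ifelse(grepl("/", class_family), sub("^[^/]*/", "", class_family), "")
  cls <- ifelse(cls %in% te_classes[1:4], cls, "Other")
  list(class = cls, family = fam)
}

#' Read a RepeatMasker .out annotation
#'
#' Standard layout: three header lines, then whitespace-delimited columns.
#' Query coordinates (1-based inclusive) become 0-based half-open; percent
#' divergence becomes a fraction in `[0, 1]`; the class/family string is
#' collapsed to one of LINE/SINE/LTR/DNA/Other.
#'
#' @param path RepeatMasker .out file.
#' @param substitution_rate substitutions/site/year used to derive ages
#'   (age = divergence / rate).
#' @return a `te_table` data.frame with columns `te_id`, `chrom`, `start`,
#'   `end`, `strand`, `class`, `family`, `subfamily`, `divergence`, `age`,
#'   `length`.
#' @export
read_repeatmasker_out <- function(path, substitution_rate = 4.5e-9) {
  lines <- readLines(path)
  if (length(lines) >= 3L) lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_te_table())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L)) stop("malformed RepeatMasker row (fewer than 14 columns) at line ",
                          which(nf < 14L)[1])
  get <- function(i) vapply(fields, `[[`, "", i)
  div <- as.numeric(get(2))
  if (any(is.na(div)) || any(div < 0)) stop("negative or missing divergence in ", path)
  qstart <- as.integer(get(6)); qend <- as.integer(get(7))
  if (any(qstart > qend)) stop("RepeatMasker row with start > end in ", path)
  strand <- ifelse(get(9) == "C", "-", "+")
  cf <- parse_te_class(get(11))
  te_table(chrom = get(5), start = qstart - 1L, end = qend,
           strand = strand, class = cf$class, family = cf$family,
           subfamily = get(10), divergence = div / 100,
           substitution_rate = substitution_rate)
}

#' Construct a TE annotation table
#'
#' @param chrom,start,end,strand,class,family,subfamily,divergence per-TE
#'   vectors (0-based half-open coordinates; divergence as a fraction).
#' @param substitution_rate substitutions/site/year for the derived age.
#' @return a `te_table` data.frame (see [read_repeatmasker_out()]).
#' @export
te_table <- function(chrom, start, end, strand = "+", class = "Other",
                     family = "", subfamily = "", divergence = 0,
                     substitution_rate = 4.5e-9) {
  n <- length(start)
  stopifnot(all(end > start), all(divergence >= 0), all(divergence <= 1))
  out <- data.frame(te_id = seq_len(n), chrom = rep_len(chrom, n),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(strand, n),
                    class = factor(rep_len(class, n), levels = te_classes),
                    family = rep_len(family, n),
                    subfamily = rep_len(subfamily, n),
                    divergence = rep_len(divergence, n),
                    stringsAsFactors = FALSE)
  out$age <- te_age(out$divergence, substitution_rate)
  out$length <- out$end - out$start
  class(out) <- c("te_table", "data.frame")
  out
}

empty_te_table <- function() {
  te_table(character(), integer(), integer())[0, ]
}

#' Write a TE table in RepeatMasker .out layout
#'
#' @param tes a `te_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(tes, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  cf <- ifelse(as.character(tes$class) %in% te_classes[1:4],
               paste0(tes$class, ifelse(nzchar(tes$family), paste0("/", tes$family), "")),
               ifelse(nzchar(tes$family), tes$family, "Unknown"))
  rows <- sprintf("%5d %5.1f  0.0  0.0  %s %8d %8d (0) %s  %-14s %-18s %6d %5d (0) %5d",
                  1000L, tes$divergence * 100,
                  tes$chrom, tes$start + 1L, tes$end,
                  ifelse(tes$strand == "-", "C", "+"),
                  tes$subfamily, cf, 1L, tes$length, tes$te_id)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read homozygous SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records with homozygous genotypes for
#' every requested strain.  Indels, multi-allelic records, heterozygous and
#' missing calls are skipped; a count of skipped records is reported via
#' `message()` and stored in the `skipped` attribute.
#'
#' @param path VCF file (plain text).
#' @param strain_names strains to extract; defaults to all sample columns.
#' @return a `snp_table` data.frame with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, and one 0/1 integer column per strain.
#' @export
read_snv_vcf <- function(path, strain_names = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr_i <- which(startsWith(body, "#CHROM"))
  if (!length(hdr_i)) stop("VCF lacks a #CHROM header line: ", path)
  hdr <- strsplit(sub("^#", "", body[hdr_i[1]]), "\t")[[1]]
  samples <- hdr[-(1:9)]
  if (is.null(strain_names)) strain_names <- samples
  missing <- setdiff(strain_names, samples)
  if (length(missing))
    stop("genotype column missing for strain(s): ", paste(missing, collapse = ", "))
  rows <- body[-seq_len(hdr_i[1])]
  rows <- rows[nzchar(rows)]
  n_skip_nonsnv <- 0L; n_skip_het <- 0L
  if (!length(rows)) {
    out <- empty_snp_table(strain_names)
    attr(out, "skipped") <- c(non_snv = 0L, het_or_missing = 0L)
    return(out)
  }
  f <- data.table::tstrsplit(rows, "\t", fixed = TRUE)
  chrom <- f[[1]]; pos1 <- as.integer(f[[2]]); ref <- f[[4]]; alt <- f[[5]]
  idx <- match(strain_names, samples) + 9L
  gt <- lapply(idx, function(i) sub(":.*$", "", f[[i]]))
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip_nonsnv <- sum(!is_snv)
  code <- function(g) ifelse(g %in% c("0/0", "0|0", "0"), 0L,
                      ifelse(g %in% c("1/1", "1|1", "1"), 1L, NA_integer_))
  gmat <- vapply(gt, code, integer(length(rows)))
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = length(rows))
  ok_gt <- rowSums(is.na(gmat)) == 0L
  n_skip_het <- sum(is_snv & !ok_gt)
  keep <- is_snv & ok_gt
  if (n_skip_nonsnv + n_skip_het > 0)
    message(sprintf("read_snv_vcf: skipped %d non-SNV and %d heterozygous/missing-genotype record(s)",
                    n_skip_nonsnv, n_skip_het))
  out <- data.frame(chrom = chrom[keep], pos = pos1[keep] - 1L,
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  for (j in seq_along(strain_names)) out[[strain_names[j]]] <- gmat[keep, j]
  out <- snp_table(out, strain_names)
  attr(out, "skipped") <- c(non_snv = n_skip_nonsnv, het_or_missing = n_skip_het)
  out
}

#' Construct / validate a SNP table
#'
#' @param df data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`
#'   plus one 0/1 column per strain.
#' @param strains character vector naming the strain columns.
#' @return a `snp_table` (df with a `strains` attribute).
#' @export
snp_table <- function(df, strains) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)),
            all(strains %in% names(df)))
  if (nrow(df)) {
    if (any(df$ref == df$alt)) stop("SNP with ref == alt")
    if (anyDuplicated(df[, c("chrom", "pos")])) stop("duplicate SNP position")
  }
  rownames(df) <- NULL
  attr(df, "strains") <- strains
  class(df) <- c("snp_table", "data.frame")
  df
}

empty_snp_table <- function(strains) {
  df <- data.frame(chrom = character(), pos = integer(),
                   ref = character(), alt = character())
  for (s in strains) df[[s]] <- integer()
  snp_table(df, strains)
}

#' Write a SNP table as a minimal VCF
#'
#' @param snps a `snp_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snps, path) {
  strains <- attr(snps, "strains")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=accessTE",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", strains), collapse = "\t")), con)
  if (nrow(snps)) {
    gcols <- vapply(strains, function(s)
      ifelse(snps[[s]] == 1L, "1/1", "0/0"), character(nrow(snps)))
    if (is.null(dim(gcols))) gcols <- matrix(gcols, nrow = nrow(snps))
    rows <- paste(snps$chrom, snps$pos + 1L, ".", snps$ref, snps$alt, ".",
                  "PASS", ".", "GT",
                  apply(gcols, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read position-weight matrices (JASPAR-like count format)
#'
#' Each record is a `>name` line followed by four lines `A [ n1 n2 ... ]`,
#' `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path PWM text file.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount smoothing pseudocount (added as `pseudocount * background`).
#' @param score_threshold hit threshold as a fraction of the maximal log-odds.
#' @return a named list of `pwm` objects (see [make_pwm()]).
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1,
                     score_threshold = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) stop("no PWM records in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    nm <- sub("^>\\s*", "", lines[starts[i]])
    block <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    rows <- lapply(block, function(ln) {
      nums <- sub("^[ACGT]\\s*\\[?\\s*", "", sub("\\]\\s*$", "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged PWM matrix for motif ", nm)
    mat <- do.call(rbind, rows)
    rownames(mat) <- substr(block, 1, 1)
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    out[[nm]] <- make_pwm(nm, mat, background = background,
                          pseudocount = pseudocount,
                          score_threshold = score_threshold)
  }
  out
}

#' Write PWMs in the JASPAR-like count format
#'
#' @param pwms a list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write a CpG methylation table
#'
#' TSV with columns `chrom`, `pos` (0-based CpG position) and one
#' methylation-fraction column per strain.
#'
#' @param path file path.
#' @return `read_cpg_table` returns a `cpg_table` data.frame.
#' @rdname cpg_io
#' @export
read_cpg_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = 1)))
  stopifnot(all(c("chrom", "pos") %in% names(dt)))
  cpg_table(dt, setdiff(names(dt), c("chrom", "pos")))
}

#' @param cpgs a `cpg_table`.
#' @rdname cpg_io
#' @export
write_cpg_table <- function(cpgs, path) {
  data.table::fwrite(as.data.frame(cpgs), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a CpG methylation table
#'
#' @param df data.frame with `chrom`, `pos` and per-strain fraction columns.
#' @param strains strain column names.
#' @return a `cpg_table` with a `strains` attribute.
#' @export
cpg_table <- function(df, strains) {
  stopifnot(all(c("chrom", "pos") %in% names(df)), all(strains %in% names(df)))
  vals <- as.matrix(df[, strains, drop = FALSE])
  if (nrow(df) && (min(vals, na.rm = TRUE) < 0 || max(vals, na.rm = TRUE) > 1))
    stop("methylation fractions must lie in [0, 1]")
  rownames(df) <- NULL
  attr(df, "strains") <- strains
  class(df) <- c("cpg_table", "data.frame")
  df
}
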