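#' Build a strain pseudo-genome
#'
#' Substitutes a strain's SNP alleles into the reference sequence.  Lengths
#' and coordinates are unchanged, so all strains share a coordinate system.
#'
#' @param reference named character vector of chromosome sequences.
#' @param snps a `snp_table` whose ref alleles match `reference`.
#' @param strain strain (genotype column) to substitute.
#' @return a named character vector: the pseudo-genome.
#' @export
build_pseudo_genome <- function(reference, snps, strain) {
  strains <- attr(snps, "strains")
  if (!strain %in% strains) stop("unknown strain: ", strain)
  out <- reference
  if (!nrow(snps)) return(out)
  unknown <- setdiff(unique(snps$chrom), names(reference))
  if (length(unknown)) stop("SNP chromosome(s) absent from reference: ",
                            paste(unknown, collapse = ", "))
  for (chr in unique(snps$chrom)) {
    sub <- snps[snps$chrom == chr, , drop = FALSE]
    have <- substring(reference[[chr]], sub$pos + 1L, sub$pos + 1L)
    bad <- which(have != sub$ref)
    if (length(bad))
      stop(sprintf("SNP ref-allele mismatch at %s:%d (VCF ref %s, genome %s)",
                   chr, sub$pos[bad[1]], sub$ref[bad[1]], have[bad[1]]))
    carry <- sub[[strain]] == 1L
    if (any(carry)) {
      s <- strsplit(out[[chr]], "")[[1]]
      s[sub$pos[carry] + 1L] <- sub$alt[carry]
      out[[chr]] <- paste(s, collapse = "")
    }
  }
  out
}

#' Diff two same-coordinate genomes
#'
#' Recovers the substitution set distinguishing `genome` from `reference`;
#' the inverse of [build_pseudo_genome()].
#'
#' @param reference,genome named character vectors with identical names and
#'   per-chromosome lengths.
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
diff_genomes <- function(reference, genome) {
  stopifnot(identical(names(reference), names(genome)))
  out <- lapply(names(reference), function(chr) {
    a <- strsplit(reference[[chr]], "")[[1]]
    b <- strsplit(genome[[chr]], "")[[1]]
    if (length(a) != length(b)) stop("length mismatch on ", chr)
    i <- which(a != b)
    data.frame(chrom = rep(chr, length(i)), pos = i - 1L,
               ref = a[i], alt = b[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
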