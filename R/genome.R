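#' Genome model: autosomes with chromosome-arm structure
#'
#' The pipeline operates on the 22 human autosomes only; sex chromosomes are
#' excluded throughout because hybridisation intensities on the allosomes are
#' confounded by patient sex. A genome build is a small data frame of
#' chromosome names, lengths and centromere positions, optionally scaled to a
#' fraction of the physical genome (all downstream statistics are proportions
#' or distances over a common territory and are scale-free).
#'
#' @param scale positive scaling factor applied to all lengths (default 1,
#'   i.e. hg19 physical lengths).
#' @return object of class `genome_build`: data frame with columns `chrom`
#'   (character "1".."22"), `length` (integer bp) and `centromere` (bp
#'   position separating the p and q arm).
#' @examples
#' g <- genome_hg19()
#' sum(as.numeric(g$length))      # ~2.88 Gb of autosomal territory
#' g10 <- genome_hg19(scale = 0.1)
#' @export
genome_hg19 <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566)
  cen <- c(125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
           59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
           17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
           26500000, 27500000, 13200000, 14700000)
  g <- data.frame(chrom = as.character(1:22),
                  length = round(len * scale),
                  centromere = round(cen * scale),
                  stringsAsFactors = FALSE)
  validate_genome(g)
}

#' Construct a genome build from chromosome lengths
#'
#' @param chrom character vector of unique autosome names.
#' @param length integer bp length per chromosome, all positive.
#' @param centromere optional bp position of the p/q boundary; defaults to
#'   the chromosome midpoint.
#' @return a `genome_build` object.
#' @export
genome_build <- function(chrom, length, centromere = NULL) {
  if (is.null(centromere)) centromere <- round(length / 2)
  g <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                  centromere = as.numeric(centromere),
                  stringsAsFactors = FALSE)
  validate_genome(g)
}

validate_genome <- function(g) {
  if (anyDuplicated(g$chrom)) stop("duplicate chromosome names in genome build")
  if (any(g$length <= 0)) stop("all chromosome lengths must be > 0")
  if (any(g$chrom %in% c("X", "Y", "chrX", "chrY", "23", "24")))
    stop("allosomes are not part of the analysis genome")
  if (any(g$centromere <= 0 | g$centromere >= g$length))
    stop("centromere positions must lie strictly inside the chromosome")
  class(g) <- c("genome_build", "data.frame")
  g
}

#' Chromosome arm table for a genome build
#'
#' @param genome a `genome_build`.
#' @return data frame with one row per arm: `chrom`, `arm` ("p"/"q"),
#'   `start`, `end` (1-based inclusive bp).
#' @export
genome_arms <- function(genome) {
  stopifnot(inherits(genome, "genome_build"))
  p <- data.frame(chrom = genome$chrom, arm = "p", start = 1,
                  end = genome$centromere, stringsAsFactors = FALSE)
  q <- data.frame(chrom = genome$chrom, arm = "q",
                  start = genome$centromere + 1, end = genome$length,
                  stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out <- out[order(match(out$chrom, genome$chrom), out$arm), ]
  rownames(out) <- NULL
  out$name <- paste0(out$chrom, out$arm)
  out
}

# order a (chrom, pos) pair by genome order; chroms not in the build sort last
genome_order <- function(genome, chrom, pos) {
  order(match(chrom, genome$chrom), pos)
}
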