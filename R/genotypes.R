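# Canonical orderings. All state vectors, gamete tables and cross tables in
# the package index genotypes by these; the orderings are frozen and tested.

TARGET_ALLELES <- c("W", "D", "R")

# unordered allele pairs (i <= j in W < D < R order)
TARGET_CLASSES <- c("WW", "WD", "WR", "DD", "DR", "RR")

# female sex-chromosome pairs: x = wild-type X, X = damaged X (has passed
# through an SDGD male and survived shredding)
FEMALE_CHROM <- c("xx", "xX", "XX")

# male sex chromosome carried alongside Y
MALE_CHROM <- c("x", "X")

# egg classes: target allele x chromosome, allele fastest
EGG_CLASSES <- c("W.x", "D.x", "R.x", "W.X", "D.X", "R.X")

# sperm classes as a 3 x 3 (allele x chromosome) layout; the (D, x) class is
# structurally zero because SDGD males only transmit damaged X chromosomes
SPERM_CHROM <- c("x", "X", "Y")

#' Canonical female genotype labels
#'
#' The 18 female genotypes are the product of the six unordered target-site
#' allele pairs (W/W, W/D, W/R, D/D, D/R, R/R) and the three sex-chromosome
#' pairs (xx, xX, XX), in that order with the chromosome index fastest.
#'
#' @return Character vector of length 18, e.g. `"WW.xx"`, `"WW.xX"`, ...
#' @export
female_genotypes <- function() {
  as.vector(t(outer(TARGET_CLASSES, FEMALE_CHROM, paste, sep = ".")))
}

#' Canonical male genotype labels
#'
#' The 12 male genotypes are the six target-site classes crossed with the
#' carried sex chromosome (wild-type x or damaged X); every male also carries
#' a Y, which is left implicit in the label.
#'
#' @return Character vector of length 12, e.g. `"WW.x"`, `"WW.X"`, ...
#' @export
male_genotypes <- function() {
  as.vector(t(outer(TARGET_CLASSES, MALE_CHROM, paste, sep = ".")))
}

# split a target class into its two alleles
target_pair <- function(target_class) {
  stopifnot(target_class %in% TARGET_CLASSES)
  strsplit(target_class, "")[[1]]
}

# number of D alleles per target class, in canonical order
d_copies <- function() c(WW = 0L, WD = 1L, WR = 0L, DD = 2L, DR = 1L, RR = 0L)

# TRUE for target classes carrying at least one D (transgenic, RFP+ analogue)
has_drive <- function() d_copies() > 0L

# TRUE for target classes with at least one functional (W) copy of the
# female-fertility target gene; dsx-null homozygotes (DD, DR, RR) are viable
# but cannot bite
has_wild_copy <- function() c(WW = TRUE, WD = TRUE, WR = TRUE,
                              DD = FALSE, DR = FALSE, RR = FALSE)

# target class label of genotype labels like "WD.xx"
geno_target <- function(labels) sub("\\..*$", "", labels)

# chromosome part of genotype labels
geno_chrom <- function(labels) sub("^.*\\.", "", labels)
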