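# Mendelian bookkeeping for balancer complementation crosses. Zygote
# classes are the four equiprobable allele combinations of a cross between
# two heterozygous parents; balancer homozygotes are lethal, so the scored
# trans-heterozygote is expected in 1/3 of the surviving progeny when it is
# fully viable.

ALLELES <- c("FlpStop_ND", "FlpStop_D", "Null", "Balancer", "WT")

genotype_key <- function(pair) paste(sort(pair), collapse = "/")

#' Specify a two-parent cross
#'
#' @param parent1,parent2 character vectors of length 2: the allele pair
#'   carried by each parent (over \code{FlpStop_ND}, \code{FlpStop_D},
#'   \code{Null}, \code{Balancer}, \code{WT}).
#' @param lethal_genotypes list of unordered allele pairs that do not
#'   survive to adulthood; the balancer homozygote is lethal and is added
#'   automatically unless \code{balancer_lethal = FALSE}.
#' @param scored_class unordered allele pair whose frequency among
#'   survivors is scored.
#' @param balancer_lethal keep the default Balancer/Balancer lethality
#'   (TRUE); set FALSE only for didactic no-lethal-class enumerations.
#' @return object of class \code{cross_spec}.
#' @examples
#' cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
#'            scored_class = c("FlpStop_ND", "Null"))
#' @export
cross_spec <- function(parent1, parent2,
                       lethal_genotypes = list(),
                       scored_class, balancer_lethal = TRUE) {
  check_pair <- function(p, what) {
    if (length(p) != 2 || !all(p %in% ALLELES)) {
      stop(what, " must be a pair of alleles from: ",
           paste(ALLELES, collapse = ", "))
    }
  }
  check_pair(parent1, "parent1")
  check_pair(parent2, "parent2")
  check_pair(scored_class, "scored_class")
  lethal_keys <- vapply(lethal_genotypes, genotype_key, character(1))
  if (balancer_lethal) {
    lethal_keys <- c(lethal_keys, genotype_key(c("Balancer", "Balancer")))
  }
  lethal_keys <- unique(lethal_keys)
  structure(
    list(parent1 = parent1, parent2 = parent2,
         lethal_keys = lethal_keys,
         scored_key = genotype_key(scored_class)),
    class = "cross_spec"
  )
}

# enumerate the 4 equiprobable zygote classes of a cross
zygote_classes <- function(cross) {
  combos <- expand.grid(a = cross$parent1, b = cross$parent2,
                        stringsAsFactors = FALSE)
  keys <- mapply(function(a, b) genotype_key(c(a, b)), combos$a, combos$b)
  tab <- table(keys) / length(keys)
  data.frame(genotype = names(tab), prob = as.numeric(tab),
             stringsAsFactors = FALSE)
}

#' Expected frequency of the scored class among surviving progeny
#'
#' Enumerates the four equiprobable zygote classes of the cross, removes
#' the lethal ones, and returns the scored class's probability conditional
#' on survival. For the standard complementation cross
#' \code{allele1/Balancer x allele2/Balancer} with the balancer homozygote
#' lethal, the scored trans-heterozygote is expected at 1/3 (33%).
#'
#' @param cross a [cross_spec()].
#' @return expected fraction in \code{[0, 1]}; 0 when the scored class is
#'   itself lethal.
#' @examples
#' cs <- cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
#'                  scored_class = c("FlpStop_ND", "Null"))
#' expected_survival(cs) # 1/3
#' @export
expected_survival <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  z <- zygote_classes(cross)
  if (cross$scored_key %in% cross$lethal_keys) return(0)
  alive <- !(z$genotype %in% cross$lethal_keys)
  if (!any(alive)) stop("all zygote classes are lethal")
  p_alive <- sum(z$prob[alive])
  sum(z$prob[alive & z$genotype == cross$scored_key]) / p_alive
}

#' Draw multinomial progeny counts for a cross
#'
#' Surviving zygote classes are sampled with their conditional Mendelian
#' probabilities; lethal classes are reported with count 0.
#'
#' @param cross a [cross_spec()].
#' @param n total number of surviving adult progeny (> 0).
#' @param seed integer seed.
#' @return data frame with columns \code{genotype}, \code{expected_prob}
#'   (conditional on survival; 0 for lethal classes), \code{count}.
#' @examples
#' cs <- cross_spec(c("FlpStop_ND", "Balancer"), c("Null", "Balancer"),
#'                  scored_class = c("FlpStop_ND", "Null"))
#' generate_cross_counts(cs, n = 300, seed = 1)
#' @export
generate_cross_counts <- function(cross, n, seed = 1L) {
  stopifnot(inherits(cross, "cross_spec"))
  if (!(n > 0)) stop("n must be > 0")
  z <- zygote_classes(cross)
  alive <- !(z$genotype %in% cross$lethal_keys)
  if (!any(alive)) stop("all zygote classes are lethal")
  probs <- ifelse(alive, z$prob, 0)
  probs <- probs / sum(probs)
  set.seed(substream_seed(seed, "cross_counts"))
  counts <- as.vector(rmultinom(1, size = n, prob = probs))
  data.frame(genotype = z$genotype, expected_prob = probs, count = counts,
             stringsAsFactors = FALSE)
}
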