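#' Simulate a Yule (pure-birth) phylogeny
#'
#' Pure-birth tree conditioned on the number of tips, via
#' \code{ape::rphylo} with death rate 0. Yule trees give realistic
#' branch-length heterogeneity with a single parameter.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (per unit time).
#' @param seed Optional integer; when given the simulation is run under
#'   this seed without disturbing the global RNG.
#' @return An ape \code{phylo}.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  sim <- function() ape::rphylo(n_tips, birth = birth_rate, death = 0)
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Evolve a binary trait along a phylogeny
#'
#' Continuous-time two-state Markov simulation: along each branch the
#' trait switches 0 -> 1 at rate \code{gain} and 1 -> 0 at rate
#' \code{loss}. This produces the phylogenetically clustered binary traits
#' (such as oxygen requirement, where anaerobes sit in discrete clades)
#' that motivate contrast-based rather than naive cross-species tests.
#'
#' @param tree Rooted ape \code{phylo} with branch lengths.
#' @param gain,loss Transition rates (>= 0, not both 0).
#' @param root_state Trait state at the root (0 or 1).
#' @param seed Optional integer seed (scoped, as in [simulate_tree()]).
#' @return Named integer vector of tip states (0/1).
#' @export
evolve_binary_trait <- function(tree, gain, loss, root_state = 0,
                                seed = NULL) {
  stopifnot(inherits(tree, "phylo"), gain >= 0, loss >= 0,
            root_state %in% c(0, 1))
  if (gain == 0 && loss == 0) {
    abort_oxymet("gain and loss rates must not both be 0",
                 "oxymet_validation_error")
  }
  run <- function() {
    ntip <- length(tree$tip.label)
    state <- rep(NA_integer_, ntip + tree$Nnode)
    state[ntip + 1L] <- as.integer(root_state)
    edges <- ape::reorder.phylo(tree, "cladewise")
    rates <- c(`0` = gain, `1` = loss)
    for (i in seq_len(nrow(edges$edge))) {
      s <- state[edges$edge[i, 1]]
      remaining <- edges$edge.length[i]
      repeat {
        r <- rates[[as.character(s)]]
        if (r <= 0) break
        wait <- rexp(1, r)
        if (wait > remaining) break
        remaining <- remaining - wait
        s <- 1L - s
      }
      state[edges$edge[i, 2]] <- s
    }
    setNames(state[seq_len(ntip)], tree$tip.label)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Thin wrapper over \code{ape::rTraitCont} (model "BM"): the neutral
#' response model under which contrast-based tests are calibrated.
#'
#' @param tree Rooted ape \code{phylo} with branch lengths.
#' @param sigma BM standard deviation per unit branch length.
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed (scoped).
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma = 1, root_value = 0, seed = NULL) {
  sim <- function() ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                    root.value = root_value)
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}
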