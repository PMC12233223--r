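# Shared fixtures built in code: random DAGs with random CPTs, and small
# hand-made networks.

# random DAG over n binary nodes (arc i -> j only for i < j), random
# strictly-positive CPT rows; deterministic given seed
random_network <- function(n_nodes, seed, p_arc = 0.4) {
  withr::with_seed(seed, {
    vars <- paste0("V", seq_len(n_nodes))
    arcs <- data.frame(parent = character(), child = character())
    if (n_nodes > 1) {
      for (j in 2:n_nodes) for (i in 1:(j - 1)) {
        if (stats::runif(1) < p_arc)
          arcs <- rbind(arcs, data.frame(parent = vars[i], child = vars[j]))
      }
    }
    net0 <- bn_network(vars, arcs, cpts = NULL, validate = FALSE)
    cpts <- lapply(vars, function(v) {
      parents <- burnoutbn:::bn_parents(net0, v)
      n_cfg <- 2^length(parents)
      p_high <- stats::runif(n_cfg, 0.05, 0.95)
      prob <- array(rbind(1 - p_high, p_high), dim = c(2, rep(2, length(parents))))
      bn_cpt(v, parents, prob)
    })
    bn_network(vars, arcs, cpts)
  })
}

# random CPTs on a fixed structure (e.g. the study DAG)
random_cpts_on <- function(structure, seed) {
  withr::with_seed(seed, {
    cpts <- lapply(names(structure$variables), function(v) {
      parents <- burnoutbn:::bn_parents(structure, v)
      n_cfg <- 2^length(parents)
      p_high <- stats::runif(n_cfg, 0.05, 0.95)
      prob <- array(rbind(1 - p_high, p_high), dim = c(2, rep(2, length(parents))))
      bn_cpt(v, parents, prob)
    })
    bn_network(structure$variables, structure$arcs, cpts)
  })
}

# hard evidence on a random subset of variables
random_evidence <- function(net, seed, max_vars = 2) {
  withr::with_seed(seed, {
    k <- sample.int(max_vars, 1)
    vars <- sample(names(net$variables), min(k, length(net$variables)))
    stats::setNames(vapply(vars, function(v) sample(net$variables[[v]], 1), ""),
                    vars)
  })
}

# two-node chain A -> B with the given distributions
chain_network <- function(p_a_low = 0.6, p_b_low_given = c(low = 0.5, high = 0.2)) {
  bn_network(
    c("A", "B"),
    data.frame(parent = "A", child = "B"),
    list(bn_cpt("A", character(), c(p_a_low, 1 - p_a_low)),
         bn_cpt("B", "A", array(c(p_b_low_given["low"], 1 - p_b_low_given["low"],
                                  p_b_low_given["high"], 1 - p_b_low_given["high"]),
                                dim = c(2, 2)))))
}

study_structure <- function() bn_network(study_variables(), study_arcs())

as_marg_vector <- function(m) unlist(unclass(m))
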