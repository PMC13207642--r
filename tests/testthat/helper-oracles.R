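# Independent oracles used across the suite.

# Brute-force nodal (admittance-matrix) impedance of a circuit tree: the
# tree is flattened into a graph of two-terminal elements, the complex
# admittance matrix is stamped, and the input impedance solved as the
# voltage at the injection node for a unit current. Entirely independent of
# the algebraic series/parallel evaluator in the package.
graph_impedance <- function(node, f) {
  edges <- list()        # list of (n1, n2, z)
  counter <- new.env(); counter$next_node <- 2L
  new_node <- function() {
    counter$next_node <- counter$next_node + 1L
    counter$next_node
  }
  element_z <- function(el, f) {
    p <- el$params
    switch(el$kind,
      resistor  = complex(real = p$R),
      capacitor = if (f == 0) complex(real = Inf) else 1 / (2i * pi * f * p$C),
      cpe       = 1 / (p$Q * (2i * pi * f)^p$n),
      inductor  = complex(imaginary = 2 * pi * f * p$L),
      warburg   = p$sigma_w * (1 - 1i) / sqrt(2 * pi * f)
    )
  }
  expand <- function(el, a, b) {
    if (el$kind == "series") {
      nodes <- c(a, replicate(length(el$children) - 1, new_node()), b)
      for (i in seq_along(el$children)) {
        expand(el$children[[i]], nodes[i], nodes[i + 1])
      }
    } else if (el$kind == "parallel") {
      for (ch in el$children) expand(ch, a, b)
    } else {
      edges[[length(edges) + 1]] <<- list(a = a, b = b, el = el)
    }
  }
  expand(node, 1L, 2L)
  vapply(f, function(ff) {
    nn <- counter$next_node
    Y <- matrix(complex(real = 0), nn, nn)
    for (e in edges) {
      z <- element_z(e$el, ff)
      y <- if (is.infinite(Mod(z))) 0 + 0i else 1 / z
      Y[e$a, e$a] <- Y[e$a, e$a] + y; Y[e$b, e$b] <- Y[e$b, e$b] + y
      Y[e$a, e$b] <- Y[e$a, e$b] - y; Y[e$b, e$a] <- Y[e$b, e$a] - y
    }
    # ground node 2, inject 1 A at node 1
    keep <- setdiff(seq_len(nn), 2L)
    rhs <- complex(real = rep(0, length(keep))); rhs[1] <- 1
    A <- Y[keep, keep, drop = FALSE]
    # symmetric Jacobi equilibration: nodal matrices mix admittances of
    # vastly different magnitude when a small series impedance meets a
    # large one, and the raw solve loses digits
    d <- 1 / sqrt(Mod(diag(A)))
    As <- A * tcrossprod(d)
    v <- d * solve(As, d * rhs)
    v <- v + d * solve(As, d * (rhs - A %*% v))
    v[1]
  }, complex(1))
}

# Random circuit tree of at most `n_el` primitive elements. Element values
# are drawn from electrochemically plausible ranges chosen so that every
# element's |Z| stays within a few decades over the 0.1 Hz - 1 kHz test
# band; wilder magnitude spreads make the *oracle's* nodal matrix (not the
# algebraic evaluator) lose precision.
random_tree <- function(n_el, allow_singular = TRUE) {
  prim <- function() {
    k <- sample(if (allow_singular) 5 else 3, 1)
    switch(k,
      ckt_resistor(10^runif(1, 1, 4)),
      ckt_capacitor(10^runif(1, -4.5, -3.5)),
      ckt_inductor(10^runif(1, 0, 1)),
      ckt_cpe(10^runif(1, -4, -3), runif(1, 0.5, 1)),
      ckt_warburg(10^runif(1, 1, 3)))
  }
  build <- function(budget) {
    if (budget <= 1) return(prim())
    split <- sample(budget - 1, 1)
    comb <- if (runif(1) < 0.5) ckt_series else ckt_parallel
    comb(build(split), build(budget - split))
  }
  build(n_el)
}

# Brute-force transfer gain of a corrosion source in one zone of the loop:
# unit current injected across the zone nodes of the working electrode,
# ammeter current read off the external branch. 3-node nodal solve,
# independent of the package's divider formula.
nodal_corrosion_gain <- function(loop, f) {
  spec <- loop$electrode
  zones <- zrasim:::electrode_zones(spec)
  zi <- lapply(zones, function(z) ckt_impedance(z$circuit, f))
  ze_counter <- electrode_impedance(spec, f)
  vapply(seq_along(f), function(i) {
    # nodes: 1 = working metal (source +), 2 = electrolyte (ground),
    # 3 = counter metal. zones: 1-2; Rs+Rshunt: 1-3 via external? No:
    # external branch from node 1 through ammeter+Rs to counter electrode
    # which faces the same electrolyte node 2.
    y_zone <- sum(vapply(zi, function(z) {
      y <- 1 / z[i]; if (is.infinite(Mod(z[i]))) 0 + 0i else y
    }, complex(1)))
    rext <- loop$Rs + loop$Rshunt
    # branch 1 -> 3 (Rs + Rshunt), branch 3 -> 2 (counter electrode)
    y13 <- if (rext == 0) NA else 1 / rext
    yc <- 1 / ze_counter[i]
    if (is.na(y13)) {
      # collapse nodes 1 and 3
      Y <- matrix(y_zone + yc, 1, 1)
      v <- solve(Y, 1 + 0i)
      v[1] * yc      # current through the counter branch = ammeter current
    } else {
      Y <- matrix(complex(real = 0), 2, 2)  # nodes 1 and 3 (2 grounded)
      Y[1, 1] <- y_zone + y13; Y[1, 2] <- -y13
      Y[2, 1] <- -y13; Y[2, 2] <- y13 + yc
      v <- solve(Y, c(1 + 0i, 0 + 0i))
      (v[1] - v[2]) * y13
    }
  }, complex(1))
}
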