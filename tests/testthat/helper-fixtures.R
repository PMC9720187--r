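# Shared small-scale fixtures, built once per test run.

fx <- new.env()

fx_high <- function() {
  if (is.null(fx$high)) fx$high <- subdivide(base_icosahedron(), 8)
  fx$high
}

fx_low <- function() {
  if (is.null(fx$low)) fx$low <- subdivide(base_icosahedron(), 2)
  fx$low
}

fx_sphere4 <- function() {
  if (is.null(fx$s4)) fx$s4 <- subdivide(base_icosahedron(), 4)
  fx$s4
}

fx_adj4 <- function() {
  if (is.null(fx$adj4)) fx$adj4 <- build_adjacency(fx_sphere4())
  fx$adj4
}

fx_mapping <- function() {
  if (is.null(fx$map)) fx$map <- nearest_assignment(fx_high(), fx_low())
  fx$map
}

fx_layout <- function() {
  if (is.null(fx$layout))
    fx$layout <- build_layout(fx_high(), fx_low(), fx_mapping(),
                              build_adjacency(fx_low()), grid_spec())
  fx$layout
}

# union-find connected components oracle: sizes of marked components
uf_cluster_sizes <- function(marked, edges) {
  par <- seq_along(marked)
  find <- function(x) { while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }; x }
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (marked[a] && marked[b]) par[find(a)] <- find(b)
  }
  if (!any(marked)) return(integer(0))
  roots <- vapply(which(marked), find, integer(1))
  sort(as.integer(table(roots)))
}

# breadth-first graph distances from one vertex
graph_distances <- function(adjacency, from) {
  d <- rep(Inf, length(adjacency))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (nb in adjacency[[v]]) if (d[nb] > d[v] + 1) {
      d[nb] <- d[v] + 1
      queue <- c(queue, nb)
    }
  }
  d
}

# decode every subject of a simulated dataset and return the accuracy maps
decode_dataset <- function(ds, layout, contrast = "1 vs 2",
                           spec = classifier_spec("svm")) {
  cfg <- attr(ds, "config")
  lapply(seq_along(ds), function(s) {
    trials <- bind_trials(lapply(seq_along(ds[[s]]$runs), function(r)
      extract_trials(ds[[s]]$runs[[r]], ds[[s]]$paradigms[[r]],
                     cfg$timepoint)))
    subject_accuracy_map(trials, layout, contrast = contrast, spec = spec,
                         subject_id = s)
  })
}

fx_high16 <- function() {
  if (is.null(fx$high16)) fx$high16 <- subdivide(base_icosahedron(), 16)
  fx$high16
}

fx_layout164 <- function() {
  if (is.null(fx$layout164))
    fx$layout164 <- build_layout(fx_high16(), fx_sphere4(),
                                 nearest_assignment(fx_high16(), fx_sphere4()),
                                 fx_adj4(), grid_spec())
  fx$layout164
}
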