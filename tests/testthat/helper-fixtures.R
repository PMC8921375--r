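# Shared fixtures, computed lazily and cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-size phantom with the complete pipeline up to PRM (the expensive part,
# shared by the registration/densitometry/acceptance tests)
phantom_pipeline <- function(seed = 7) {
  cached(paste0("pipe", seed), {
    pair <- make_phantom_pair(seed = seed)
    config <- pipeline_config()
    regions_i <- segment_subject(pair$insp, config)
    regions_e <- segment_subject(pair$exp, config)
    reg <- register_pair(pair$insp, pair$exp, regions_i, regions_e, config)
    par <- parenchyma_mask(regions_i)
    prm <- prm_classify(pair$insp, reg$coreg, par, thresholds(), regions_i)
    list(pair = pair, truth = pair$truth, config = config,
         regions_i = regions_i, regions_e = regions_e, reg = reg,
         parenchyma = par, prm = prm)
  })
}

# truth PRM class array (1 normal / 2 fSAD / 3 emphysema) on the insp grid
truth_prm_classes <- function(truth) {
  cls <- array(1L, dim(truth$lesion_labels))
  cls[truth$lesion_labels == 1L] <- 3L
  cls[truth$lesion_labels == 2L] <- 2L
  cls
}

# small random lesion masks for property tests
random_lesion_mask <- function(dim3 = c(24, 24, 24), p = 0.12, seed = 1) {
  set.seed(seed)
  m <- array(runif(prod(dim3)) < p, dim = dim3)
  # a couple of solid blobs so clusters have interior depth
  for (b in 1:2) {
    c0 <- sample(5:(dim3[1] - 5), 3)
    r <- sample(2:4, 1)
    g <- index_grids_list(dim3)
    m <- m | array((g$i - c0[1])^2 + (g$j - c0[2])^2 + (g$k - c0[3])^2 <= r^2,
                   dim3)
  }
  m
}

index_grids_list <- function(d) {
  list(
    i = array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d),
    j = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d),
    k = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  )
}

# brute-force erosion-depth oracle: repeated erosion with array shifts only
brute_force_depth <- function(mask) {
  d <- dim(mask)
  shift1 <- function(a, axis, by) {
    idx <- seq_len(d[axis]) + by
    pad <- idx < 1 | idx > d[axis]
    idx <- pmin(pmax(idx, 1L), d[axis])
    sel <- rep(list(quote(expr = )), 3)
    sel[[axis]] <- idx
    out <- do.call(`[`, c(list(a), sel, list(drop = FALSE)))
    selp <- rep(list(quote(expr = )), 3)
    selp[[axis]] <- which(pad)
    if (any(pad)) out <- do.call(`[<-`, c(list(out), selp, list(FALSE)))
    out
  }
  erode1 <- function(m) {
    out <- m
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      out <- out & shift1(shift1(shift1(m, 1, di), 2, dj), 3, dk)
    }
    out
  }
  depth <- array(-1L, d)
  cur <- mask
  lvl <- 0L
  while (any(cur)) {
    depth[cur] <- lvl
    cur <- erode1(cur)
    lvl <- lvl + 1L
  }
  depth
}

make_geometry <- function(d, spacing = c(1, 1, 1)) {
  volume3d(array(-800, d), spacing)
}

expect_json_identical <- function(a, b) {
  expect_identical(
    jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(b, auto_unbox = TRUE, digits = NA)
  )
}
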