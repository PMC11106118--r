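# shared fixture builders; all fixtures are generated in code

# solid axis-aligned square component, n x n pixels at (row0, col0)
squareComponent <- function(n, row0 = 1L, col0 = 1L) {
  as.matrix(expand.grid(row = row0:(row0 + n - 1L),
                        col = col0:(col0 + n - 1L)))
}

# digitised disc component of radius r (pixel centers within r of center)
discComponent <- function(r, center = c(r + 2L, r + 2L)) {
  span <- 1:(2L * r + 3L)
  cc <- as.matrix(expand.grid(row = span, col = span))
  cc[(cc[, 1] - center[1])^2 + (cc[, 2] - center[2])^2 <= r^2, ,
     drop = FALSE]
}

# random connected blob grown from a seed pixel (for property tests)
randomBlob <- function(n_px, seed) {
  set.seed(seed)
  pts <- matrix(c(25L, 25L), 1L, 2L)
  while (nrow(pts) < n_px) {
    base <- pts[sample(nrow(pts), 1L), ]
    step <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    cand <- pmin(pmax(base + step, 1L), 50L)
    if (!any(pts[, 1] == cand[1] & pts[, 2] == cand[2])) {
      pts <- rbind(pts, cand)
    }
  }
  colnames(pts) <- c("row", "col")
  pts
}

# oracle: Feret diameter as brute-force max pairwise distance over the
# four corners of every pixel (O(n^2), small components only)
bruteFeret <- function(coords) {
  xy <- cbind(coords[, 2], coords[, 1])
  corners <- do.call(rbind, lapply(list(c(-.5, -.5), c(-.5, .5),
                                        c(.5, -.5), c(.5, .5)),
                                   function(o) sweep(xy, 2, -o)))
  max(dist(corners))
}

# uniform-colour ScanImage from a brightness matrix
greyScan <- function(b, pixel_size_um = 5) {
  scanImage(array(rep(b, 3L), c(dim(b), 3L)), pixel_size_um)
}

# population of n well-separated bright discs for end-to-end tests
discPopulation <- function(n, size_um = 60, tpb = 200, red = 0.5) {
  data.frame(class_label = rep("disc", n), truth = rep("MP", n),
             shape_class = rep("spheroid", n), size_um = rep(size_um, n),
             aspect = rep(1, n), tpb = rep(tpb, n),
             red_fraction = rep(red, n), stringsAsFactors = FALSE)
}

# minimal particle-record table for aggregation tests
recordTable <- function(feret, tpb = 100, red = 0.5, shape = "fragment",
                        suspect = TRUE, mass = 1) {
  n <- length(feret)
  data.frame(particle_id = sprintf("r%03d", seq_len(n)),
             feret_max_um = feret,
             shape_class = rep_len(shape, n),
             fluor_group = rep_len("medium", n),
             mp_suspect = rep_len(suspect, n),
             size_class = if (n) assignSizeClass(feret) else character(0),
             mass_ug = rep_len(mass, n), stringsAsFactors = FALSE)
}
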