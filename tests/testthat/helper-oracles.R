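# Independent oracles used across the suite. Everything here is written
# against the definitions directly (enumeration, sliding windows, boundary
# tracing) and never calls the package code paths it is checking.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (i in seq_len(n)) {
      q <- c(p[seq_len(i - 1L)], n, p[seq.int(i, length.out = n - i)])
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

# minimal total cost over all one-to-one assignments (square matrix)
brute_assignment_min <- function(C) {
  n <- nrow(C)
  best <- Inf
  for (p in perms(n)) {
    s <- sum(C[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# local mean by direct double loop with replicated edges
sliding_mean <- function(img, w) {
  h <- (w - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    rr <- pmin(pmax(seq(r - h, r + h), 1), ny)
    cc <- pmin(pmax(seq(c - h, c + h), 1), nx)
    out[r, c] <- mean(img[rr, cc])
  }
  out
}

# Moore-neighbour boundary tracing (Jacob's stopping criterion); returns the
# closed 8-connected chain length of a single-component 0/1 matrix
moore_chain_length <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  fg <- which(m != 0)
  if (length(fg) < 2) return(0)
  nb <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
               ncol = 2, byrow = TRUE)
  at <- function(r, c) r >= 1 && r <= ny && c >= 1 && c <= nx && m[r, c] != 0
  s <- fg[1]
  sr <- (s - 1) %% ny + 1; sc <- (s - 1) %/% ny + 1
  pts <- list(c(sr, sc))
  cur <- c(sr, sc); bdir <- 1
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((bdir - 1 + k) %% 8) + 1
      r <- cur[1] + nb[d, 1]; c <- cur[2] + nb[d, 2]
      if (at(r, c)) {
        ddr <- cur[1] - r; ddc <- cur[2] - c
        for (q in 1:8) if (nb[q, 1] == ddr && nb[q, 2] == ddc) { bdir <- q; break }
        bdir <- (bdir %% 8) + 1
        cur <- c(r, c)
        found <- TRUE
        break
      }
    }
    if (!found) return(0)
    if (cur[1] == sr && cur[2] == sc) break
    pts[[length(pts) + 1L]] <- cur
    if (length(pts) > 10 * length(fg) + 100) stop("tracing runaway")
  }
  P <- do.call(rbind, pts)
  n <- nrow(P)
  d <- P - P[c(2:n, 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

oracle_perimeter <- function(comp) {
  p <- moore_chain_length(comp)
  if (p == 0) 2 * sqrt(pi * sum(comp != 0)) else p
}

oracle_circularity <- function(comp) {
  oracle_perimeter(comp)^2 / (4 * pi * sum(comp != 0))
}

# brute-force re-application of the four nucleus-filter rules to each
# connected component by direct pixel arithmetic; returns the accepted
# components as a list of sorted pixel-index vectors
brute_filter_oracle <- function(mask, min_area = 3, max_circularity = 2,
                                max_area = 60, max_circularity_split = 2.5,
                                min_area_split = 4) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask != 0)))))
  accepted <- list()
  for (lb in setdiff(unique(as.vector(lab)), 0)) {
    comp <- matrix(as.integer(lab == lb), nrow(mask), ncol(mask))
    area <- sum(comp)
    if (area < min_area) next                               # (i)
    if (oracle_circularity(comp) >= max_circularity) next   # (ii)
    if (area > max_area) {                                  # (iii)
      sl <- woundtrack::split_clusters(comp)
      for (s in setdiff(unique(as.vector(sl)), 0)) {
        piece <- matrix(as.integer(sl == s), nrow(mask), ncol(mask))
        if (sum(piece) < min_area_split) next               # (iv)
        if (oracle_circularity(piece) > max_circularity_split) next
        accepted[[length(accepted) + 1L]] <- sort(which(piece != 0))
      }
    } else {
      accepted[[length(accepted) + 1L]] <- sort(which(comp != 0))
    }
  }
  accepted
}

label_pixel_sets <- function(label_image) {
  fg <- which(label_image > 0)
  unname(lapply(split(fg, label_image[fg]), sort))
}

same_label_sets <- function(a, b) {
  key <- function(s) paste(s, collapse = ",")
  setequal(vapply(a, key, ""), vapply(b, key, ""))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_perm_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  r <- rank(pooled)
  us <- apply(idx, 2, function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# random blob mask for filter-cascade property tests
random_blob_mask <- function(n = 48, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  k <- EBImage::makeBrush(7, "Gaussian", sigma = 1.5)
  zs <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(z)), k)))
  m <- matrix(as.integer(zs > stats::quantile(zs, 0.86)), n, n)
  # sprinkle some specks and a bar so every rule fires now and then
  m[sample(n * n, 3)] <- 1L
  if (seed %% 3 == 0) m[sample(5:(n - 5), 1), 4:(n - 4)] <- 1L
  m
}

disk_mask <- function(n, cx, cy, r) {
  matrix(as.integer((col(matrix(0, n, n)) - cx)^2 +
                    (row(matrix(0, n, n)) - cy)^2 <= r^2), n, n)
}

# small tracked-objects table for toy tracking scenarios
toy_objects <- function(df) {
  out <- data.frame(frame = df$frame, object_id = df$object_id,
                    x = df$x, y = df$y,
                    area = if (is.null(df$area)) 30 else df$area,
                    mean_intensity = if (is.null(df$mean_intensity)) 500
                      else df$mean_intensity,
                    circularity = if (is.null(df$circularity)) 1.05
                      else df$circularity)
  out
}
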