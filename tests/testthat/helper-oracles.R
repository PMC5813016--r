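# Independent brute-force oracles and small shared fixtures. These are
# deliberately written from the operator definitions, not by reusing package
# internals, so implementation and oracle stay on separate routes.

# Exhaustive per-pixel NMS: candidate scan + equal-valued plateau collapse.
nms_oracle <- function(img, radius, threshold) {
  nr <- nrow(img)
  nc <- ncol(img)
  cand <- matrix(FALSE, nr, nc)
  for (r in 1:nr) {
    for (c in 1:nc) {
      v <- img[r, c]
      if (v < threshold) next
      rs <- max(1, r - radius):min(nr, r + radius)
      cs <- max(1, c - radius):min(nc, c + radius)
      if (all(img[rs, cs] <= v)) cand[r, c] <- TRUE
    }
  }
  seen <- matrix(FALSE, nr, nc)
  peaks <- NULL
  for (c in 1:nc) {
    for (r in 1:nr) {
      if (!cand[r, c] || seen[r, c]) next
      v <- img[r, c]
      comp <- matrix(c(r, c), 1)
      seen[r, c] <- TRUE
      q <- list(c(r, c))
      while (length(q)) {
        p <- q[[1]]
        q <- q[-1]
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- p[1] + dr
            cc <- p[2] + dc
            if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
            if (cand[rr, cc] && !seen[rr, cc] && img[rr, cc] == v) {
              seen[rr, cc] <- TRUE
              comp <- rbind(comp, c(rr, cc))
              q <- c(q, list(c(rr, cc)))
            }
          }
        }
      }
      peaks <- rbind(peaks, comp[order(comp[, 1], comp[, 2])[1], ])
    }
  }
  if (is.null(peaks)) return(matrix(integer(0), 0, 2))
  peaks <- peaks[order(peaks[, 1], peaks[, 2]), , drop = FALSE]
  dimnames(peaks) <- NULL
  peaks
}

# Exhaustive 256-threshold between-class-variance Otsu.
otsu_oracle <- function(img) {
  v <- as.integer(img)
  best <- -Inf
  bt <- 0L
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    s <- (length(g0) / length(v)) * (length(g1) / length(v)) *
      (mean(g0) - mean(g1))^2
    if (s > best + 1e-12) {
      best <- s
      bt <- t
    }
  }
  bt
}

# Direct min/max-over-disk erosion and dilation (border ignored).
erode_oracle <- function(img, radius) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- img
  for (r in 1:nr) {
    for (c in 1:nc) {
      vals <- c()
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          if (dr^2 + dc^2 > radius^2) next
          rr <- r + dr
          cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
            vals <- c(vals, img[rr, cc])
          }
        }
      }
      out[r, c] <- min(vals)
    }
  }
  out
}

dilate_oracle <- function(img, radius) {
  -erode_oracle(-img, radius)
}

tophat_oracle <- function(img, radius) {
  img - dilate_oracle(erode_oracle(img, radius), radius)
}

# Count truth centres matched by a detected peak within `tol` px (Euclidean).
match_count <- function(peaks, truth, tol) {
  if (nrow(truth) == 0L || nrow(peaks) == 0L) return(0L)
  d <- sqrt(outer(truth[, 1], peaks[, 1], "-")^2 +
              outer(truth[, 2], peaks[, 2], "-")^2)
  sum(apply(d, 1, min) <= tol)
}

detection_pr <- function(field, cfg = pipeline_config(), tol = 1) {
  d <- detect_puncta(field, cfg)
  truth <- field$truth$puncta_centers
  m <- match_count(d$peaks, truth, tol)
  c(precision = if (nrow(d$peaks)) m / nrow(d$peaks) else 1,
    recall = if (nrow(truth)) m / nrow(truth) else 1,
    n_detected = nrow(d$peaks))
}

# Quiet, small hierarchical fit used in several binding tests.
fit_hier_quick <- function(dataset, seed = 1L, n_iter = 4000L) {
  fit_binding_hier(dataset, n_iter = n_iter, burn_in = n_iter / 2,
                   seed = seed, warn = FALSE)
}

binding_specific <- function(spec) {
  tab <- generate_binding(spec)
  specific_binding(tab[tab$condition == "total", ],
                   tab[tab$condition == "nsb", ])
}
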