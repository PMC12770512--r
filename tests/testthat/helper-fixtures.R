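# Shared fixtures: small seeded synthetic datasets and reference oracles
# written independently of the implementation under test.

small_synth_config <- function(...) {
  synth_config(image_size = c(96, 96), ...)
}

# a tiny in-memory manifest (no files needed for split arithmetic)
fake_manifest <- function(counts, classes = synth_classes()) {
  stopifnot(length(counts) == length(classes))
  dplyr::bind_rows(purrr::map2(classes, counts, function(cl, n) {
    if (n == 0) return(tibble::tibble(path = character(), label = character()))
    tibble::tibble(path = sprintf("%s_%05d.png", cl, seq_len(n)), label = cl)
  }))
}

# --- independent oracles ----------------------------------------------

# brute-force Otsu: double loop over candidates, explicit class stats
oracle_otsu <- function(img) {
  v <- as.vector(img)
  if (length(unique(v)) == 1L) return(unique(v))
  best_t <- 0L; best_var <- -1
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) {
      best_var <- bc; best_t <- t
    }
  }
  best_t
}

# BFS flood-fill labelling of a logical mask
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1L) %% h) + 1L; pc <- ((p - 1L) %/% h) + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- pr + nb[k, 1]; c2 <- pc + nb[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- c(queue, (c2 - 1L) * h + r2)
        }
      }
    }
  }
  lab
}

oracle_remove_small <- function(mask, min_px, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  matrix(lab %in% which(sizes >= min_px), nrow(mask), ncol(mask))
}

# naive per-pixel sorted-neighbourhood median with edge replication
oracle_median3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - 1):(i + 1), 1), h)
      ci <- pmin(pmax((j - 1):(j + 1), 1), w)
      out[i, j] <- sort(as.vector(img[ri, ci]))[5]
    }
  }
  out
}

# per-definition confusion metrics (independent of the implementation)
oracle_metrics <- function(cm) {
  k <- nrow(cm); total <- sum(cm)
  res <- list(accuracy = sum(diag(cm)) / total, precision = numeric(k),
              recall = numeric(k), f1 = numeric(k))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    res$precision[i] <- p; res$recall[i] <- r
    res$f1[i] <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  }
  res
}

# plain global histogram equalisation (reference for single-tile CLAHE)
oracle_global_he <- function(img) {
  cdf <- cumsum(tabulate(img + 1L, 256L)) / length(img)
  v <- 255 * cdf[img + 1L]
  matrix(floor(v + 0.5), nrow(img), ncol(img))
}
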