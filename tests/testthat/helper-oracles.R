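# Independent oracles: deliberately naive reimplementations used only to
# check the package's algorithms. They share no code with R/.

# O(cells x true-cells) dilation by pairwise center distances
oracle_dilate <- function(mask, distance_m) {
  v <- mask$values
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(FALSE, nr, nc)
  tr <- which(v, arr.ind = TRUE)
  if (nrow(tr) == 0L) return(out)
  d2 <- distance_m^2
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      dd <- ((i - tr[, 1])^2 + (j - tr[, 2])^2) * mask$cell_size_m^2
      if (any(dd <= d2 + 1e-9)) out[i, j] <- TRUE
    }
  }
  out
}

# stack-based flood fill; returns the label matrix (labels in discovery order)
oracle_flood_fill <- function(v, diagonal = FALSE) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  steps <- if (diagonal) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (sj in seq_len(nc)) for (si in seq_len(nr)) {
    if (!v[si, sj] || lab[si, sj] > 0L) next
    k <- k + 1L
    stack <- list(c(si, sj)); lab[si, sj] <- k
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (s in seq_len(nrow(steps))) {
        ni <- cur[1] + steps[s, 1]; nj <- cur[2] + steps[s, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            v[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- k
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# closed-form OLS slope
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

rand_mask <- function(nr, nc, p = 0.1, cell = 30) {
  as_mask(matrix(stats::runif(nr * nc) < p, nr, nc), cell_size_m = cell)
}

# long (crop_id, buffer_km, value) form of a published wide table, crop rows
# only (Total and the current column dropped)
published_long <- function(wide) {
  crops <- wide[wide$crop != "Total", setdiff(names(wide), "current")]
  out <- tidyr::pivot_longer(crops, -crop, names_to = "buffer_km",
                             values_to = "value")
  out$buffer_km <- as.numeric(sub("km_", "", out$buffer_km))
  names(out)[names(out) == "crop"] <- "crop_id"
  out
}

# seven-crop screening fixture: the target roster plus three foods that must
# be rejected (low score, falling consumption, falling production)
screening_fixture <- function() {
  roster <- c("dates", "kiwis", "broccoli", "lima beans", "sweet potatoes",
              "great northern beans", "mushrooms")
  sub <- c("fruit", "fruit", "dark green", "starchy", "red and orange",
           "beans and peas", "other")
  foods <- tibble::tibble(
    food_id = c(roster, "reject_score", "reject_cons", "reject_prod"),
    name = food_id,
    myplate_subgroup = c(sub, "other", "other", "other"),
    fiber_g = c(rep(6, 7), 0.2, 6, 6),
    calcium_mg = c(rep(60, 7), 2, 60, 60),
    magnesium_mg = c(rep(40, 7), 1, 40, 40),
    potassium_mg = c(rep(500, 7), 20, 500, 500)
  )
  years <- 2008:2016
  mk <- function(fid, type, slope) {
    tibble::tibble(food_id = fid, series_type = type, year = years,
                   value = 100 + slope * (years - 2008))
  }
  series <- dplyr::bind_rows(
    lapply(foods$food_id, function(f) {
      cs <- if (f == "reject_cons") -0.1 else 2
      ps <- if (f == "reject_prod") -0.5 else 3
      dplyr::bind_rows(mk(f, "consumption", cs), mk(f, "production", ps))
    })
  )
  list(foods = foods, series = series, roster = roster)
}
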