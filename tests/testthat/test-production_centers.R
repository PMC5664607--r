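acreage_tbl <- function(df_wide, years = 2002:2012) {
  # df_wide: county_id, state, ha (constant over years)
  tidyr::expand_grid(i = seq_len(nrow(df_wide)), year = years) |>
    dplyr::mutate(county_id = df_wide$county_id[i], state = df_wide$state[i],
                  acreage = df_wide$ha[i]) |>
    dplyr::select(-i)
}

test_that("national shares reproduce hand-computed fractions and sum to one", {
  solo <- acreage_tbl(tibble::tibble(county_id = "only", state = "CA",
                                     ha = 123))
  expect_equal(mean_national_share(solo)$share, 1)

  # a dominant county holding 55% of national acreage
  fix <- acreage_tbl(tibble::tibble(
    county_id = c("riverside", "b", "c"), state = c("CA", "AZ", "NM"),
    ha = c(5500, 3000, 1500)))
  sh <- mean_national_share(fix, 2002:2012)
  expect_equal(sh$share[sh$county_id == "riverside"], 0.55)
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)

  # 4-county spreadsheet oracle with uneven years (missing year = 0 acreage)
  tbl <- tibble::tibble(
    county_id = c("a", "a", "b", "b", "c", "d"),
    state = "XX",
    year = c(2002, 2003, 2002, 2003, 2002, 2003),
    acreage = c(10, 20, 5, 15, 8, 12)
  )
  sh <- mean_national_share(tbl, 2002:2003)
  means <- c(a = 15, b = 10, c = 4, d = 6)
  expect_equal(sh$share[match(names(means), sh$county_id)],
               unname(means / 35))
  expect_error(mean_national_share(dplyr::mutate(tbl, acreage = 0)),
               "degenerate-data")
})

test_that("abutting eligible counties merge into single centers", {
  sh <- tibble::tibble(
    county_id = c("johnston", "nash", "sampson", "wilson", "calhoun",
                  "merced", "tiny"),
    share = c(0.08, 0.07, 0.06, 0.06, 0.12, 0.11, 0.04))
  adj <- tibble::tibble(a = c("johnston", "nash", "sampson", "tiny"),
                        b = c("nash", "wilson", "johnston", "calhoun"))
  centers <- identify_centers(sh, adj, threshold = 0.05)
  expect_equal(nrow(centers), 3)
  nc_grp <- centers$county_ids[[which(centers$n_counties == 4)]]
  expect_setequal(nc_grp, c("johnston", "nash", "sampson", "wilson"))
  expect_equal(centers$share[which(centers$n_counties == 4)], 0.27)
  expect_true(all(diff(centers$share) <= 0))  # sorted by descending share
  # no eligible county -> empty roster
  expect_equal(nrow(identify_centers(sh, adj, threshold = 0.5)), 0)
  # threshold monotonicity: raising it never adds counties
  n_at <- function(th) sum(identify_centers(sh, adj, th)$n_counties)
  ths <- c(0.02, 0.05, 0.08, 0.2)
  expect_true(all(diff(sapply(ths, n_at)) <= 0))
})

test_that("merging equals a union-find oracle and ignores input order", {
  set.seed(71)
  for (k in 1:10) {
    n <- 8
    ids <- sprintf("c%d", 1:n)
    sh <- tibble::tibble(county_id = ids, share = runif(n, 0, 0.25))
    pairs <- t(combn(ids, 2))
    pick <- runif(nrow(pairs)) < 0.25
    adj <- tibble::tibble(a = pairs[pick, 1], b = pairs[pick, 2])
    centers <- identify_centers(sh, adj, threshold = 0.10)
    # union-find oracle over eligible counties
    elig <- ids[sh$share >= 0.10]
    parent <- stats::setNames(elig, elig)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    if (nrow(adj)) for (e in seq_len(nrow(adj))) {
      if (adj$a[e] %in% elig && adj$b[e] %in% elig) {
        parent[[find(adj$a[e])]] <- find(adj$b[e])
      }
    }
    want <- if (length(elig)) {
      unname(lapply(split(elig, vapply(elig, find, "")), sort))
    } else list()
    got <- lapply(centers$county_ids, sort)
    expect_setequal(lapply(got, paste, collapse = "+"),
                    lapply(want, paste, collapse = "+"))
    # permutation invariance
    perm <- sh[sample(n), ]
    centers2 <- identify_centers(perm, adj, threshold = 0.10)
    expect_setequal(centers2$center_id, centers$center_id)
  }
})

test_that("county adjacency from a label raster uses the rook rule", {
  v <- matrix(NA_real_, 4, 4)
  v[1:2, 1:2] <- 1; v[3:4, 1:2] <- 2; v[1:2, 3:4] <- 3
  v[4, 4] <- 4  # touches 3 only diagonally via (3,4)? no: (3,4) is NA
  cr <- grid_raster(v, 30, kind = "categorical")
  adj <- county_adjacency(cr, c(a = 1, b = 2, c = 3, d = 4))
  key <- paste(adj$a, adj$b)
  expect_setequal(key, c("a b", "a c"))  # d corner-touches nothing by edge
})

test_that("scenario regions are nested and grow by the exact dilation count", {
  m <- as_mask(matrix(FALSE, 40, 40), cell_size_m = 30)
  m$values[16:25, 16:25] <- TRUE
  expect_identical(expand_center(m, 0)$values, m$values)
  grown <- suppressWarnings(expand_center(m, 0.06))  # 60 m = 2 cells
  expect_identical(grown$values, oracle_dilate(m, 60))
  areas <- vapply(c(0, 5, 10, 15, 20),
                  function(b) mask_area_ha(expand_center(m, b)), numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_error(expand_center(m, -3), "non-negative")
  expect_warning(expand_center(m, 7), "canonical")
})

test_that("clip masks restrict expanded regions", {
  m <- as_mask(matrix(FALSE, 20, 20), cell_size_m = 1000)
  m$values[10, 10] <- TRUE
  clip <- as_mask(matrix(FALSE, 20, 20), cell_size_m = 1000)
  clip$values[, 1:10] <- TRUE
  r <- expand_center(m, 5, clip = clip)
  expect_true(all(which(r$values, arr.ind = TRUE)[, 2] <= 10))
})
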