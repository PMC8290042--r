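test_that("incidence applies unique-user semantics and the period window", {
  asn <- make_assignment(rep("u1", 10), rep("A", 10))
  inc <- build_incidence(asn, YEAR)
  expect_equal(inc$place_users$user_count, 1)  # 10 events, one user

  asn2 <- make_assignment(c("u1", "u1", "u2"), c("A", "B", "A"))
  inc2 <- build_incidence(asn2, YEAR)
  expect_equal(inc2$place_users$user_count[inc2$place_users$place_id == "A"], 2)
  expect_equal(inc2$place_users$user_count[inc2$place_users$place_id == "B"], 1)

  # all events after the period end -> empty incidence
  late <- make_assignment("u1", "A",
                          timestamp = as.POSIXct("2021-01-01", tz = "UTC"))
  inc3 <- build_incidence(late, YEAR)
  expect_equal(nrow(inc3$user_places), 0)

  # half-open: an event exactly at the end instant is excluded, at start kept
  edge <- make_assignment(
    c("u1", "u2"), c("A", "A"),
    timestamp = as.POSIXct(c("2019-01-01 00:00:00", "2020-01-01 00:00:00"),
                           tz = "UTC")
  )
  inc4 <- build_incidence(edge, YEAR)
  expect_equal(inc4$user_places$user_id, "u1")
})

test_that("the index equals shared users over the geometric mean", {
  # S_A = 100, S_B = 400, S_AB = 20 -> 20/sqrt(40000) = 0.1, from
  # enumerated users
  users_a <- sprintf("a%03d", 1:80)            # only A
  users_b <- sprintf("b%03d", 1:380)           # only B
  users_ab <- sprintf("s%03d", 1:20)           # shared
  asn <- make_assignment(
    c(users_a, users_b, users_ab, users_ab),
    c(rep("A", 80), rep("B", 380), rep("A", 20), rep("B", 20))
  )
  pm <- compute_pci(build_incidence(asn, YEAR))
  expect_equal(pm$place_summary$user_count, c(100, 400))
  expect_equal(pm$shared_users$value, 20)
  expect_equal(pm$pci$value, 0.1)
})

test_that("disjoint user sets yield no record (index zero is implicit)", {
  asn <- make_assignment(c("u1", "u2"), c("A", "B"))
  pm <- compute_pci(build_incidence(asn, YEAR))
  expect_equal(nrow(pm$pci), 0)
})

test_that("connectivity matches the brute-force oracle on random fixtures", {
  for (seed in 1:10) {
    n_places <- sample(3:20, 1)
    asn <- random_assignment(n_places, n_users = sample(20:150, 1), seed = seed)
    pm <- compute_pci(build_incidence(asn, YEAR))
    oracle <- brute_force_pci(asn, YEAR)
    got <- as.data.frame(pm$pci[, c("place_i", "place_j", "value")])
    want <- oracle$edges[, c("place_i", "place_j", "pci")]
    names(want)[3] <- "value"
    rownames(want) <- NULL
    expect_identical(got, want)
    expect_identical(
      as.data.frame(pm$place_summary),
      data.frame(place_id = oracle$user_counts$place_id,
                 user_count = as.integer(oracle$user_counts$user_count))
    )
  }
})

test_that("index invariants hold on random incidence sets", {
  for (seed in 11:25) {
    asn <- random_assignment(12, 80, seed = seed)
    pm <- compute_pci(build_incidence(asn, YEAR))
    s <- setNames(pm$place_summary$user_count, pm$place_summary$place_id)
    expect_true(all(pm$pci$value >= 0 & pm$pci$value <= 1))
    expect_true(all(pm$shared_users$value <=
                      pmin(s[pm$pci$place_i], s[pm$pci$place_j])))
    # stored canonically: one row per unordered pair
    expect_true(all(pm$pci$place_i < pm$pci$place_j))
    # relabeling users leaves the matrix unchanged
    relabeled <- asn
    relabeled$user_id <- chartr("u", "z", asn$user_id)
    pm2 <- compute_pci(build_incidence(relabeled, YEAR))
    expect_equal(as.data.frame(pm2$pci), as.data.frame(pm$pci))
    # event order irrelevant
    pm3 <- compute_pci(build_incidence(asn[rev(seq_len(nrow(asn))), ], YEAR))
    expect_equal(as.data.frame(pm3$pci), as.data.frame(pm$pci))
  }
})

test_that("more shared users at fixed margins strictly increases the index", {
  # base: A = {u1,u2,u3}, B = {u1,u4,u5,u6}  -> S_A=3, S_B=4, S_AB=1
  base <- make_assignment(
    c("u1", "u1", "u2", "u3", "u4", "u5", "u6"),
    c("A", "B", "A", "A", "B", "B", "B")
  )
  # more: A = {u1,u2,u3}, B = {u1,u2,u5,u6} -> same margins, S_AB=2
  more <- make_assignment(
    c("u1", "u1", "u2", "u2", "u3", "u5", "u6"),
    c("A", "B", "A", "B", "A", "B", "B")
  )
  pm1 <- compute_pci(build_incidence(base, YEAR))
  pm2 <- compute_pci(build_incidence(more, YEAR))
  expect_equal(as.data.frame(pm1$place_summary),
               as.data.frame(pm2$place_summary))
  expect_gt(pm2$pci$value[1], pm1$pci$value[1])
  expect_equal(pm1$pci$value[1], 1 / sqrt(12))
  expect_equal(pm2$pci$value[1], 2 / sqrt(12))
})

test_that("directional index is shared users over the origin count", {
  users_a <- sprintf("a%03d", 1:80)
  users_b <- sprintf("b%03d", 1:380)
  users_ab <- sprintf("s%03d", 1:20)
  asn <- make_assignment(
    c(users_a, users_b, users_ab, users_ab),
    c(rep("A", 80), rep("B", 380), rep("A", 20), rep("B", 20))
  )
  inc <- build_incidence(asn, YEAR)
  dir <- compute_directional_pci(inc)
  ab <- dir$value[dir$place_i == "A" & dir$place_j == "B"]
  ba <- dir$value[dir$place_i == "B" & dir$place_j == "A"]
  expect_equal(ab, 0.2)    # 20/100
  expect_equal(ba, 0.05)   # 20/400
  expect_equal(sqrt(ab * ba), 0.1)  # geometric mean = symmetric index
})

test_that("directional-symmetric consistency holds for every pair", {
  asn <- random_assignment(10, 120, seed = 31)
  inc <- build_incidence(asn, YEAR)
  pm <- compute_pci(inc)
  dir <- compute_directional_pci(inc)
  key <- paste(dir$place_i, dir$place_j)
  for (r in seq_len(nrow(pm$pci))) {
    fwd <- dir$value[key == paste(pm$pci$place_i[r], pm$pci$place_j[r])]
    rev <- dir$value[key == paste(pm$pci$place_j[r], pm$pci$place_i[r])]
    expect_equal(sqrt(fwd * rev), pm$pci$value[r])
  }
  # boundary case: all of a place's users visit the other place
  asn2 <- make_assignment(c("u1", "u1", "u2"), c("A", "B", "B"))
  dir2 <- compute_directional_pci(build_incidence(asn2, YEAR))
  expect_equal(dir2$value[dir2$place_i == "A" & dir2$place_j == "B"], 1)
})

test_that("home inference uses mode, then first observation, then id", {
  ts <- function(d) as.POSIXct(d, tz = "UTC")
  asn <- tibble::tibble(
    user_id = c(rep("u1", 10), rep("u2", 10), "u3"),
    timestamp = c(ts(sprintf("2019-01-%02d", 1:10)),
                  ts(c("2019-02-01", "2019-01-05", "2019-02-02", "2019-02-03",
                       "2019-02-04", "2019-01-06", "2019-01-07", "2019-01-08",
                       "2019-01-09", "2019-01-10")),
                  ts("2019-03-01")),
    place_id = c(rep("A", 8), "B", "B",             # u1: 8 A vs 2 B
                 rep(c("B", "A"), 5),               # u2: 5-5 tie, A seen first
                 "C")                               # u3: single event
  )
  home <- infer_home(asn)
  expect_equal(home$home[home$user_id == "u1"], "A")
  expect_equal(home$home[home$user_id == "u2"], "A")
  expect_equal(home$home[home$user_id == "u3"], "C")
})

test_that("copresence person-days follow the pair combinatorics", {
  ts <- as.POSIXct("2019-07-04 09:00", tz = "UTC")
  asn <- tibble::tibble(
    user_id = rep("u1", 3),
    timestamp = ts + 1:3 * 3600,  # same UTC day
    place_id = c("A", "B", "C")
  )
  mv <- compute_person_day_movements(asn, YEAR, mode = "copresence")
  expect_equal(nrow(mv), 3)   # C(3,2) pairs
  expect_true(all(mv$value == 1))
  expect_setequal(paste(mv$place_i, mv$place_j),
                  c("A B", "A C", "B C"))
})

test_that("home-based person-days count distinct user-day destinations", {
  home <- tibble::tibble(user_id = c("u1", "u2", "u3"),
                         home = c("A", "A", "B"))
  ts <- function(d, h = 12) as.POSIXct(paste0(d, " ", h, ":00"), tz = "UTC")
  asn <- tibble::tibble(
    user_id = c(rep("u1", 4), rep("u2", 3), "u3"),
    timestamp = c(ts("2019-01-01"), ts("2019-02-01"), ts("2019-02-01", 18),
                  ts("2019-03-01"),
                  ts("2019-04-01"), ts("2019-04-02"), ts("2019-04-03"),
                  ts("2019-05-01")),
    place_id = c("A", "B", "B", "B",      # u1: home A; B on 2 distinct days
                 "A", "A", "A",           # u2: never leaves home -> 0
                 "B")                     # u3: home B, event in B -> 0
  )
  mv <- compute_person_day_movements(asn, YEAR, mode = "home_based",
                                     home = home)
  # hand enumeration: only u1 contributes, (A,B) on 2019-02-01 and 2019-03-01
  expect_equal(nrow(mv), 1)
  expect_equal(mv$place_i, "A")
  expect_equal(mv$place_j, "B")
  expect_equal(mv$value, 2)
  expect_error(compute_person_day_movements(asn, YEAR, mode = "home_based"),
               "requires a home table")
})

test_that("copresence totals conserve the user-day pair count", {
  for (seed in 41:50) {
    set.seed(seed)
    n <- 200
    asn <- tibble::tibble(
      user_id = sprintf("u%02d", sample(15, n, replace = TRUE)),
      timestamp = as.POSIXct("2019-01-01", tz = "UTC") +
        sample(0:20, n, replace = TRUE) * 86400 + sample(0:86399, n, TRUE),
      place_id = sprintf("p%d", sample(6, n, replace = TRUE))
    )
    mv <- compute_person_day_movements(asn, YEAR, mode = "copresence")
    # independent conservation total: sum over user-days of C(m, 2)
    ud <- unique(data.frame(u = asn$user_id,
                            d = as.Date(asn$timestamp, tz = "UTC"),
                            p = asn$place_id))
    m <- tapply(ud$p, paste(ud$u, ud$d), function(p) length(unique(p)))
    expect_equal(sum(mv$value), sum(choose(m, 2)))
  }
})

test_that("min-user filter drops thin places with their edges", {
  # place C has 4 users, below the default threshold of 5
  asn <- make_assignment(
    c(sprintf("a%d", 1:6), sprintf("b%d", 1:5), sprintf("c%d", 1:4),
      "a1", "c1"),
    c(rep("A", 6), rep("B", 5), rep("C", 4), "B", "A")
  )
  pm <- compute_pci(build_incidence(asn, YEAR))
  expect_true("C" %in% pm$place_summary$place_id)
  f5 <- filter_min_users(pm)   # default 5
  expect_false("C" %in% f5$place_summary$place_id)
  expect_false(any(f5$pci$place_i == "C" | f5$pci$place_j == "C"))
  # edges among surviving places are untouched
  expect_true(any(f5$pci$place_i == "A" & f5$pci$place_j == "B"))

  expect_equal(as.data.frame(filter_min_users(pm, 0)$pci),
               as.data.frame(pm$pci))
  f_all <- filter_min_users(pm, 100)
  expect_equal(nrow(f_all$place_summary), 0)
  expect_equal(nrow(f_all$pci), 0)
})
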