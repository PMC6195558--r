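# build a COM-distance series and matching occupancy/count signals directly
mkSeries <- function(values, dtNs = 1, label = "com:x-y") {
  data.frame(time_ns = (seq_along(values) - 1) * dtNs, value = values,
             label = label, stringsAsFactors = FALSE)
}

# occupancy table with one pair whose per-window formation follows `on`
mkPairTable <- function(onByWindow, windowNs, label = "B:ARG340--A:GLU542") {
  nw <- length(onByWindow)
  windows <- data.frame(start_ns = (seq_len(nw) - 1) * windowNs,
                        end_ns = seq_len(nw) * windowNs,
                        label = sprintf("w%d", seq_len(nw)))
  pairs <- data.frame(chainA = "B", resnoA = 340L, resnameA = "ARG",
                      chainB = "A", resnoB = 542L, resnameB = "GLU",
                      label = label, stringsAsFactors = FALSE)
  new("OccupancyTable", pairs = pairs,
      occupancy = matrix(as.numeric(onByWindow), 1), windows = windows)
}

test_that("a constant series is all closed and monotone signals annotate no steps", {
  s <- mkSeries(rep(30, 500))
  tl <- classifyStates(s, c(0, 100))
  expect_true(all(states(tl) == "closed"))
  cnt <- mkSeries(rep(4, 500), label = "hbonds")
  tab <- mkPairTable(rep(1, 10), 50)
  tl2 <- annotateSteps(tl, cnt, tab)
  expect_equal(nrow(steps(tl2)), 0L)
})

test_that("a noiseless 5 A step turns open at the step with latency under one smoothing window", {
  v <- c(rep(30, 500), rep(35, 500))
  tl <- classifyStates(mkSeries(v), c(0, 100), openOffset = 5, smoothNs = 10)
  st <- states(tl)
  onset <- frameTimes(tl)[which(st == "open")[1]]
  expect_true(all(st[1:495] == "closed"))
  expect_true(all(st[510:1000] == "open"))
  expect_lte(abs(onset - 500), 10)   # detection latency < one smoothing window
  expect_equal(attr(tl, "baseline_A"), 30)
  expect_error(classifyStates(mkSeries(v), c(2000, 2100)), "configuration error")
})

test_that("step-dip-rise series segments as closed/open/transient/open", {
  v <- c(rep(30, 500), rep(35, 170), rep(31, 130), rep(35, 200))
  tl <- classifyStates(mkSeries(v), c(0, 100), openOffset = 5, smoothNs = 4,
                       dwellNs = 150)
  r <- rle(states(tl))
  expect_equal(r$values, c("closed", "open", "transient", "open"))
})

test_that("the four-step mechanism is annotated from count, state and key-pair signals", {
  # schedule: count 4 -> 2 at t1 = 200; open (pair lost) at t2 = 500;
  # re-attachment with pair re-formed at t3 = 670; final open at t4 = 800
  n <- 1000
  cnt <- mkSeries(c(rep(4, 200), rep(2, 300), rep(0, 170), rep(1, 130), rep(0, 200)),
                  label = "hbonds")
  com <- mkSeries(c(rep(30, 500), rep(35, 170), rep(31, 130), rep(35, 200)))
  onByWindow <- c(rep(1, 10), rep(0, 3), c(0.6, 1, 1), rep(0, 4))  # 50-ns windows
  tab <- mkPairTable(onByWindow, 50)
  tl <- classifyStates(com, c(0, 100), openOffset = 5, smoothNs = 4, dwellNs = 150)
  tl <- annotateSteps(tl, cnt, tab)
  sdf <- steps(tl)
  expect_equal(sdf$step, 1:4)
  expect_true(all(diff(sdf$onset_ns) > 0))            # strict ordering
  expect_lte(abs(sdf$onset_ns[1] - 200), 10)
  expect_lte(abs(sdf$onset_ns[2] - 500), 10)
  expect_lte(abs(sdf$onset_ns[3] - 670), 10)
  expect_lte(abs(sdf$onset_ns[4] - 800), 10)
  # idempotence: annotating again yields identical steps
  tl2 <- annotateSteps(tl, cnt, tab)
  expect_equal(steps(tl2), sdf)
  # absent key pair: warning, steps fall back to count/state signals
  expect_warning(annotateSteps(tl, cnt, tab, keyPairs = "B:XXX1--A:YYY2"),
                 "absent from occupancy table")
})

test_that("random planted schedules are recovered within the smoothing window", {
  set.seed(61)
  smoothNs <- 10
  for (i in 1:25) {
    n <- 800
    stepAt <- sample(200:600, 1)
    stepSize <- runif(1, 4, 8)
    noise <- runif(1, 0, 0.2) * stepSize
    v <- c(rep(30, stepAt), rep(30 + stepSize, n - stepAt)) + rnorm(n, sd = noise)
    tl <- classifyStates(mkSeries(v), c(0, 100), openOffset = stepSize * 0.8,
                         smoothNs = smoothNs)
    onset <- frameTimes(tl)[which(states(tl) == "open")[1]]
    expect_lte(abs(onset - stepAt), smoothNs)
  }
})

test_that("timeline JSON export run-length encodes states and lists steps", {
  v <- c(rep(30, 50), rep(36, 50))
  tl <- classifyStates(mkSeries(v), c(0, 20), openOffset = 5, smoothNs = 4)
  cnt <- mkSeries(c(rep(4, 50), rep(0, 50)), label = "hbonds")
  tl <- annotateSteps(tl, cnt, mkPairTable(c(1, 0), 50), changeWindowNs = 20)
  p <- tempfile(fileext = ".json")
  writeTimelineJSON(tl, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_true(all(c("segments", "steps") %in% names(j)))
  expect_equal(sum(j$segments$state == "open"), 1L)
  expect_true(1 %in% j$steps$step)
})
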