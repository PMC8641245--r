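test_that("the worked association example reproduces exactly", {
    st <- csnStatistic(n = 100, nr = 10, nt = 10, nrt = 4)
    expect_identical(st$rho, 0.03)
    expect_equal(st$z, sqrt(11), tolerance = 1e-15)
    expect_equal(st$p, 4.56e-4, tolerance = 5e-3)   # 4.56E-04 to 3 s.f.
})

test_that("the statistic handles independence and a second worked case", {
    # joint occupancy equal to the product of marginals: no association
    st0 <- csnStatistic(n = 100, nr = 10, nt = 10, nrt = 1)
    expect_equal(st0$rho, 0)
    expect_equal(st0$z, 0)
    expect_equal(st0$p, 0.5)
    # direct evaluation of the definition as oracle
    st <- csnStatistic(n = 50, nr = 5, nt = 5, nrt = 3)
    expect_equal(st$rho, 0.05)
    expect_equal(st$z, 35 / 9, tolerance = 1e-12)
    expect_equal(st$p, stats::pnorm(35 / 9, lower.tail = FALSE))
    expect_equal(st$p, 5.0e-5, tolerance = 2e-2)
})

test_that("the statistic is symmetric in the two axes and monotone in nrt", {
    expect_identical(csnStatistic(n = 80, nr = 8, nt = 12, nrt = 5),
                     csnStatistic(n = 80, nr = 12, nt = 8, nrt = 5))
    z <- vapply(0:8, function(k) csnStatistic(n = 80, nr = 8, nt = 8,
                                              nrt = k)$z, numeric(1))
    expect_true(all(diff(z) > 0))
})

test_that("degenerate and invalid counts are rejected", {
    expect_error(csnStatistic(n = 10, nr = 10, nt = 5, nrt = 2),
                 "degenerate")
    expect_error(csnStatistic(n = 10, nr = 4, nt = 4, nrt = 5), "invalid")
    expect_error(csnStatistic(n = 1, nr = 1, nt = 1, nrt = 1), "2 cells")
})

test_that("neighborhood boxes have the stated occupancy and members", {
    # 0.1 * 100 = 10 cells per box on continuous data
    set.seed(1)
    x <- rnorm(100); y <- rnorm(100)
    nc <- neighborhoodCounts(x, y, k = 17, boxFraction = 0.1)
    expect_identical(nc$nr, 10L)
    expect_identical(nc$nt, 10L)
    expect_true(17 %in% nc$rBox && 17 %in% nc$tBox)

    # tiny dataset: boxes degenerate to the focal cell
    nc1 <- neighborhoodCounts(rnorm(10), rnorm(10), k = 4,
                              boxFraction = 0.1)
    expect_identical(nc1$rBox, 4L)
    expect_identical(nc1$tBox, 4L)
    expect_identical(nc1$nrt, 1L)

    # hand-checked example with a distance tie on both axes
    nc2 <- neighborhoodCounts(c(0, 1, 2, 3, 9), c(9, 3, 2, 1, 0), k = 3,
                              boxFraction = 0.6)
    expect_identical(nc2$nr, 3L)
    expect_identical(nc2$rBox, c(2L, 3L, 4L))
    expect_identical(nc2$tBox, c(2L, 3L, 4L))
    expect_identical(nc2$nrt, 3L)
})

test_that("boxes match a sort-based brute-force builder on random data", {
    set.seed(7)
    for (rep in 1:25) {
        x <- sample(c(rnorm(12), rep(0, 8)))   # dropout-style ties
        k <- sample.int(20, 1)
        nbox <- sample(2:6, 1)
        got <- neighborhoodCounts(x, x, k, boxFraction = nbox / 20)
        expect_identical(got$rBox, oracleBox(x, k, nbox))
    }
})

test_that("ties at the box boundary enter or leave together", {
    x <- c(5, 5, 5, 5, 1, 2, 8, 9, 9, 3)
    nc <- neighborhoodCounts(x, x, k = 1, boxFraction = 0.2)
    # minimum occupancy 2, but the focal tie group has 4 equal values
    expect_identical(nc$rBox, c(1L, 2L, 3L, 4L))
    expect_identical(nc$nr, 4L)
})

test_that("box arguments are validated", {
    expect_error(neighborhoodCounts(1:5, 1:4, 2), "same length")
    expect_error(neighborhoodCounts(1:5, 1:5, 9), "out of range")
    expect_error(neighborhoodCounts(1:5, 1:5, 2, boxFraction = 0),
                 "boxFraction")
})
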