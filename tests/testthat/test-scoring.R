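test_that("gene p-values match the pooled t-test, with degenerate rules", {
    m <- rbind(G1 = c(1, 2, 3, 1, 2, 3),
               G2 = c(1, 2, 3, 4, 5, 6),
               G3 = c(5, 5, 5, 5, 5, 5),
               G4 = c(7, 7, 7, 5, 5, 5))
    se <- makeSE(m, 3, 3)
    expect_equal(genePValue(se, "G1"), 1)                  # identical groups
    expect_equal(genePValue(se, "G2"), 0.02131164, tolerance = 1e-6)
    expect_equal(genePValue(se, "G3"), 1)                  # constant equal
    expect_equal(genePValue(se, "G4"), 1e-300)             # constant unequal
    expect_error(genePValue(se, "NOPE"), "not in expression")

    ## agrees with stats::t.test across random rows (both flavours)
    set.seed(31)
    mm <- matrix(rnorm(200), 10, 20,
                 dimnames = list(paste0("R", 1:10), NULL))
    se2 <- makeSE(mm, 12, 8)
    for (g in rownames(mm)) {
        ref <- t.test(mm[g, 1:12], mm[g, 13:20], var.equal = TRUE)$p.value
        expect_equal(genePValue(se2, g), ref, tolerance = 1e-12)
        refW <- t.test(mm[g, 1:12], mm[g, 13:20])$p.value
        expect_equal(genePValue(se2, g, test = "welch"), refW,
                     tolerance = 1e-12)
    }
})

test_that("pair correlations follow the covariance formula per group", {
    m <- rbind(X = c(1, 2, 3, 1, 2, 4),
               Y = c(1, 2, 3, 1, 3, 3),
               Z = c(3, 2, 1, 2, 2, 2))
    se <- makeSE(m, 3, 3)
    expect_equal(pairPCC(se, "X", "X", "CASE"), 1)
    expect_equal(pairPCC(se, "X", "Z", "CASE"), -1)
    ## textbook covariance oracle on the control group
    x <- c(1, 2, 4); y <- c(1, 3, 3)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pairPCC(se, "X", "Y", "CONTROL"), r)
    expect_equal(r, 0.755928946, tolerance = 1e-8)
    ## constant vector: 0 with warning
    expect_warning(r0 <- pairPCC(se, "Z", "X", "CONTROL"), "constant")
    expect_equal(r0, 0)
})

test_that("triplet scores are the p-product and |correlation-change| product", {
    sim <- tinyScenario(seed = 17)
    sc <- scoreTriplets(sim$expr, sim$truth$null)
    ## independent direct-formula recomputation per record
    for (i in seq_len(nrow(sc))) {
        pI <- genePValue(sim$expr, sc$immune[i])
        pN <- genePValue(sim$expr, sc$inflammation[i])
        pD <- genePValue(sim$expr, sc$disease[i])
        expect_equal(sc$scoreDif[i], pI * pN * pD, tolerance = 1e-12)
        d1 <- pairPCC(sim$expr, sc$immune[i], sc$inflammation[i], "CASE") -
            pairPCC(sim$expr, sc$immune[i], sc$inflammation[i], "CONTROL")
        d2 <- pairPCC(sim$expr, sc$immune[i], sc$disease[i], "CASE") -
            pairPCC(sim$expr, sc$immune[i], sc$disease[i], "CONTROL")
        d3 <- pairPCC(sim$expr, sc$inflammation[i], sc$disease[i], "CASE") -
            pairPCC(sim$expr, sc$inflammation[i], sc$disease[i], "CONTROL")
        expect_equal(sc$scorePCC[i], abs(d1 * d2 * d3), tolerance = 1e-12)
    }
    ## bounds
    expect_true(all(sc$scoreDif > 0 & sc$scoreDif <= 1))
    expect_true(all(sc$scorePCC >= 0 & sc$scorePCC <= 8))
})

test_that("rank combination matches hand-computed ranks and is monotone", {
    sc <- S4Vectors::DataFrame(scoreDif = c(0.001, 0.5, 0.9),
                               scorePCC = c(2.0, 0.1, 0.5))
    out <- combineRanks(sc)
    expect_equal(out$rankDif, c(3, 2, 1))
    expect_equal(out$rankPCC, c(3, 1, 2))
    expect_equal(out$finalScore, c(3, 1.5, 1.5))

    one <- combineRanks(S4Vectors::DataFrame(scoreDif = 0.2,
                                             scorePCC = 0.3))
    expect_equal(one$finalScore, 1)

    tied <- combineRanks(S4Vectors::DataFrame(scoreDif = rep(0.5, 4),
                                              scorePCC = rep(0.2, 4)))
    expect_true(all(tied$finalScore == tied$finalScore[1]))

    ## order-invariance and strict monotonicity in scoreDif
    set.seed(8)
    df <- S4Vectors::DataFrame(scoreDif = runif(50), scorePCC = runif(50, 0, 8))
    a <- combineRanks(df)
    perm <- sample(50)
    b <- combineRanks(df[perm, ])
    expect_equal(b$finalScore, a$finalScore[perm])
    df2 <- df
    df2$scoreDif[10] <- df2$scoreDif[10] / 10   # more dysregulated
    expect_gte(combineRanks(df2)$finalScore[10], a$finalScore[10])
})

test_that("rank combination agrees with direct recomputation on bulk records", {
    set.seed(123)
    n <- 1000
    df <- S4Vectors::DataFrame(scoreDif = 10^runif(n, -12, 0),
                               scorePCC = runif(n, 0, 8))
    out <- combineRanks(df)
    ## independent re-derivation via order statistics
    expect_equal(out$rankDif, n + 1 - rank(df$scoreDif))
    expect_equal(out$rankPCC, rank(df$scorePCC))
    expect_equal(out$finalScore,
                 ((n + 1 - rank(df$scoreDif)) + rank(df$scorePCC)) / 2)
})

test_that("selection is strict at alpha and builds the induced subnetwork", {
    sim <- tinyScenario(seed = 23)
    ts <- sim$truth$planted
    sc <- combineRanks(scoreTriplets(sim$expr, ts))
    sc$permP <- c(0.04, 0.05, 0.06)
    dys <- selectDysregulated(sc, sim$catalog, alpha = 0.05)
    expect_equal(nrow(records(dys)), 1L)            # strict <
    expect_equal(igraph::vcount(networkGraph(dys)), 3L)
    expect_equal(igraph::ecount(networkGraph(dys)), 3L)

    sc$permP <- rep(1, 3)
    none <- selectDysregulated(sc, sim$catalog, alpha = 0.05)
    expect_equal(nrow(records(none)), 0L)
    expect_equal(igraph::vcount(networkGraph(none)), 0L)
})

test_that("rank concordance counts selected triplets in the top block", {
    sc <- S4Vectors::DataFrame(
        immune = paste0("I", 1:10), inflammation = paste0("N", 1:10),
        disease = paste0("D", 1:10), finalScore = 10:1)
    ## top-4 selected exactly: 100%
    expect_equal(rankConcordance(sc, 1:4), 100)
    ## 4 selected, 3 in top 4: 75%
    expect_equal(rankConcordance(sc, c(1, 2, 3, 8)), 75)
    expect_equal(rankConcordance(sc, 1L), 100)
    expect_error(rankConcordance(sc, integer()), "empty")
})
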