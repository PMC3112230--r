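tidyTable <- function() {
    rbind(
        data.frame(sample = "s1", replicate = rep(1:2, each = 2),
                   lipid_class = "CL",
                   species = rep(c("72:8", "72:7"), 2),
                   concentration = c(1, 0, 0, 1)),
        data.frame(sample = "s1", replicate = 1, lipid_class = "PG",
                   species = c("16:0", "18:1"), concentration = c(3, 1)),
        data.frame(sample = "s1", replicate = 1, lipid_class = "PC_sn2",
                   species = "18:2", concentration = 5))
}

test_that("tidy tables read back with validated, ASCII-normalized species", {
    tf <- withr::local_tempfile(fileext = ".csv")
    tab <- tidyTable()
    tab$species[5] <- "16∶0"   # Unicode ratio separator on input
    write.csv(tab, tf, row.names = FALSE)
    rec <- readConcentrationTable(tf)
    expect_equal(nrow(rec), nrow(tab))
    expect_true(all(rec$species[rec$lipid_class == "PG"] %in%
                    c("16:0", "18:1")))
})

test_that("invalid concentrations and classes are rejected", {
    tf <- withr::local_tempfile(fileext = ".csv")
    bad <- tidyTable()
    bad$concentration[1] <- -1
    write.csv(bad, tf, row.names = FALSE)
    expect_error(readConcentrationTable(tf), "negative")

    bad <- tidyTable()
    bad$lipid_class[5] <- "SM"
    write.csv(bad, tf, row.names = FALSE)
    expect_error(readConcentrationTable(tf), "PE_sn2")
})

test_that("wide tables pivot to the tidy record shape", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    wide <- data.frame(sample = "s1", lipid_class = "CL",
                       species = c("72:8", "72:7"),
                       rep1 = c(2, 2), rep2 = c(1, 3))
    write.table(wide, tf, sep = "\t", row.names = FALSE, quote = FALSE)
    rec <- readConcentrationTable(tf, format = "wide")
    expect_equal(nrow(rec), 4L)
    expect_setequal(unique(rec$replicate), 1:2)
    expect_equal(rec$concentration[rec$replicate == 2], c(1, 3))
})

test_that("synthetic datasets round-trip bit-exactly through write/read", {
    pools <- sampleDonorPools(5, seed = 11)
    tr <- syntheticTruth(pools, weights = c(PG = 0.3, PC_sn2 = 0.4,
                                            PE_sn2 = 0.3),
                         sigma = 0.003, seed = 11)
    ds <- generateDataset(tr, mode = "proportional")
    tf <- withr::local_tempfile(fileext = ".csv")
    writeSyntheticDataset(ds, tf)
    rec <- readConcentrationTable(tf)
    expect_identical(rec$concentration, ds$table$concentration)
    expect_identical(rec$species, ds$table$species)
})

test_that("buildSample normalizes per replicate, then averages", {
    one <- data.frame(sample = "s", replicate = 1, lipid_class = "CL",
                      species = c("72:8", "72:7"), concentration = c(2, 2))
    one <- rbind(one, data.frame(sample = "s", replicate = 1,
                                 lipid_class = "PG", species = "18:1",
                                 concentration = 1))
    expect_equal(unname(peakValues(clProfile(buildSample(one)))),
                 c(0.5, 0.5))

    ds <- buildSample(tidyTable())
    expect_equal(unname(peakValues(clProfile(ds))), c(0.5, 0.5))
    expect_equal(ds@nReplicates, 2L)
    expect_equal(unname(probs(donorPools(ds)$PG)), c(0.75, 0.25))
})

test_that("replicate averaging equals independent recomputation on random tables", {
    set.seed(42)
    species <- c("72:8", "74:9", "76:10")
    tab <- expand.grid(replicate = 1:3, species = species,
                       stringsAsFactors = FALSE)
    tab$sample <- "s"; tab$lipid_class <- "CL"
    tab$concentration <- runif(nrow(tab), 0.1, 5)
    tab <- rbind(tab, data.frame(replicate = 1, species = "18:1",
                                 sample = "s", lipid_class = "PG",
                                 concentration = 2))
    ds <- buildSample(tab)
    # independent recomputation: row-normalize each replicate, then mean
    m <- sapply(1:3, function(r) {
        v <- tab$concentration[tab$replicate == r & tab$lipid_class == "CL"]
        names(v) <- tab$species[tab$replicate == r & tab$lipid_class == "CL"]
        v[sort(names(v))] / sum(v)
    })
    expect_equal(unname(peakValues(clProfile(ds))),
                 unname(rowMeans(m)[order(rownames(m))]))
    expect_lt(abs(sum(peakValues(clProfile(ds))) - 1), 1e-9)
})

test_that("replicate order does not change the result and absences count as zero", {
    tab <- tidyTable()
    shuffled <- tab[rev(seq_len(nrow(tab))), ]
    expect_equal(peakValues(clProfile(buildSample(tab))),
                 peakValues(clProfile(buildSample(shuffled))))

    # species present in only one replicate is a structural zero elsewhere
    miss <- tab[-2, ]  # drop 72:7 from replicate 1
    ds <- buildSample(miss)
    expect_equal(unname(peakValues(clProfile(ds))), c(0.5, 0.5))
})

test_that("degenerate replicates are rejected", {
    dup <- rbind(tidyTable(),
                 data.frame(sample = "s1", replicate = 1,
                            lipid_class = "CL", species = "72:8",
                            concentration = 1))
    expect_error(buildSample(dup), "duplicated species")

    zero <- tidyTable()
    zero$concentration[zero$lipid_class == "PG"] <- 0
    expect_error(buildSample(zero), "zero total")
})
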