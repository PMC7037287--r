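make_gaussian_classes <- function(seed, centers, n_per = 8, sd = 0.3,
                                  p = 2) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * p, mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per, p)))
  colnames(x) <- c("Cu", "Pb")[seq_len(p)]
  list(x = x, labels = rep(rownames(centers), each = n_per))
}

test_that("two separated classes load on a single axis at 100%", {
  cls <- make_gaussian_classes(1, rbind(A = c(0, 0), B = c(10, 10)))
  fit <- lda_fit(cls$x, cls$labels)
  expect_equal(length(fit$explained_pct), 1)
  expect_equal(fit$explained_pct, 100)
  expect_equal(fit$accuracy_pct, 100)
})

test_that("three classes give two ordered axes summing to 100%", {
  cls <- make_gaussian_classes(2, rbind(A = c(0, 0), B = c(6, 0),
                                        C = c(0, 4)))
  fit <- lda_fit(cls$x, cls$labels)
  expect_equal(length(fit$explained_pct), 2)
  expect_gt(fit$explained_pct[1], fit$explained_pct[2])
  expect_gt(fit$explained_pct[2], 0)
  expect_equal(sum(fit$explained_pct), 100)
  expect_equal(rowSums(fit$confusion), c(A = 8, B = 8, C = 8),
               ignore_attr = TRUE)
})

test_that("degenerate feature matrices are rejected with advice", {
  cls <- make_gaussian_classes(3, rbind(A = c(0, 0), B = c(5, 5)))
  xx <- cbind(cls$x, Zn = cls$x[, 1]) # collinear copy
  expect_error(lda_fit(xx, cls$labels, standardize = FALSE), "collinear")
  expect_error(lda_fit(cls$x, rep("A", nrow(cls$x))), "two classes")
})

test_that("leave-one-out is perfect on separated and chance on identical", {
  cls <- make_gaussian_classes(4, rbind(A = c(0, 0), B = c(12, 0)))
  cv <- crossvalidate(cls$x, cls$labels)
  expect_equal(cv$cv_accuracy_pct, 100)
  # no information: identical feature vectors, jittered to avoid singularity
  set.seed(8)
  x0 <- matrix(rnorm(48 * 2, sd = 1), 48, 2,
               dimnames = list(NULL, c("Cu", "Pb")))
  lab <- rep(c("A", "B", "C"), each = 16)
  cv0 <- crossvalidate(x0, lab)
  expect_lt(cv0$cv_accuracy_pct, 60) # near chance (33%)
})

test_that("cross-validated accuracy does not increase with noise", {
  acc_at <- function(cv_noise) {
    mean(vapply(1:5, function(s) {
      cfg <- synthetic_config(seed = s, cv_noise = cv_noise,
                              elements = c("Cu", "Zn", "Pb", "Cd"),
                              loq = c(Cu = 0, Zn = 0, Pb = 0, Cd = 0))
      d <- generate_dataset(cfg, emit = "replicates")
      f <- element_features(d, c("must", "wine"),
                            elements = c("Cu", "Zn", "Pb", "Cd"))
      crossvalidate(f$x, f$labels)$cv_accuracy_pct
    }, numeric(1)))
  }
  accs <- vapply(c(0.02, 0.3, 1.5), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("k-fold refuses folds that lose an entire class", {
  cls <- make_gaussian_classes(5, rbind(A = c(0, 0), B = c(8, 0)))
  folds <- ifelse(cls$labels == "A", 1, 2)
  expect_error(crossvalidate(cls$x, cls$labels, scheme = "k_fold",
                             folds = folds), "entire class")
})

test_that("identical items merge at height zero; nearest pair merges first", {
  prof <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  colnames(prof) <- c("Cu", "Pb")
  den <- hcluster(prof, standardize = FALSE)
  expect_equal(min(den$hclust$height), 0)
  line <- rbind(p0 = c(0, 0), p1 = c(1, 0), p10 = c(10, 0))
  colnames(line) <- c("Cu", "Pb")
  den2 <- hcluster(line, linkage = "single", standardize = FALSE)
  expect_equal(sort(den2$hclust$merge[1, ]),
               sort(-match(c("p0", "p1"), rownames(line))))
})

test_that("dendrogram leaves, cuts and Newick export are consistent", {
  prof <- soil_profile_matrix(soil_tbl)
  den <- hcluster(prof)
  expect_setequal(den$labels, rownames(prof))
  expect_equal(unname(cut_profiles(den, nrow(prof))),
               seq_len(nrow(prof)))
  expect_equal(length(unique(cut_profiles(den, 1))), 1)
  expect_true(all(diff(den$hclust$height) >= -1e-9)) # monotone merges
  tree <- ape::read.tree(text = den$newick)
  expect_setequal(gsub("_", " ", tree$tip.label), rownames(prof))
})

test_that("soil profiles split the remote area from the smelter areas", {
  prof <- soil_profile_matrix(soil_tbl)
  k2 <- cut_profiles(hcluster(prof), 2)
  remote <- grepl("^Simleul", names(k2))
  expect_equal(length(unique(k2[remote])), 1)
  expect_equal(length(unique(k2[!remote])), 1)
  expect_true(k2[remote][1] != k2[!remote][1])
})

test_that("censored cells are imputed as LOQ/2 in the feature matrix", {
  f <- element_features(bev_tbl, "must", elements = c("Cu", "Co"),
                        loq = c(Co = 0.0001215 / 1000))
  expect_true(all(f$x[, "Co"] == 0.0001215 / 2000))
})
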