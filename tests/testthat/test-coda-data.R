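test_that("coda construction validates ICIs and labels", {
  cd <- coda(c(0.2, 0.3), type = "1+1+3", clan = "EC1")
  expect_equal(cd$icis, c(0.2, 0.3))
  expect_error(coda(numeric(0)), "non-empty")
  expect_error(coda(c(0.2, -0.1)), "positive")
  expect_error(coda(0.2, type = ""), "non-empty")
})

write_toy_table <- function(path, rows) {
  writeLines(c("ici_1,ici_2,ici_3,type,clan,whale", rows), path)
}

test_that("coda tables parse with padding, missing labels, and clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_table(path, c(
    "0.2,0.3,,A,EC1,w1",
    "0.25,0.25,0.25,B,EC2,w2",
    "0.4,0,0,A,,w1"
  ))
  ds <- read_coda_table(path)
  expect_length(ds, 3)
  expect_equal(sapply(ds$codas, function(cd) length(cd$icis)), c(2, 3, 1))
  expect_true(is.na(ds$codas[[3]]$clan))
  expect_equal(label_vocabulary(ds, "type"), c("A", "B"))

  write_toy_table(path, "0.2,abc,,A,EC1,w1")
  expect_error(read_coda_table(path), "row 1")

  write_toy_table(path, "0.2,0.3,,A,EC1,w1")
  expect_error(read_coda_table(path, column_map = list(ici_prefix = "ici",
                                                       type = "nope")),
               "nope")
  expect_error(read_coda_table(path, column_map = list(bogus = "x")), "bogus")
})

test_that("packed ICI columns parse and tables round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("icis,type", "0.2;0.3;0.1,A", "0.5;0.4,B"), path)
  ds <- read_coda_table(path, column_map = list(ici_packed = "icis",
                                                type = "type"))
  expect_equal(ds$codas[[1]]$icis, c(0.2, 0.3, 0.1))
  expect_equal(ds$codas[[2]]$type, "B")

  out <- withr::local_tempfile(fileext = ".csv")
  write_coda_table(ds, out)
  ds2 <- read_coda_table(out)
  expect_equal(lapply(ds2$codas, `[[`, "icis"),
               lapply(ds$codas, `[[`, "icis"))
})

make_labelled_ds <- function(counts, len = 4) {
  codas <- list()
  for (lab in names(counts)) {
    for (i in seq_len(counts[[lab]])) {
      codas[[length(codas) + 1L]] <-
        coda(rep(0.2, len), type = lab, clan = lab, whale = lab)
    }
  }
  coda_dataset(codas)
}

test_that("cohort filters apply click-count, length, label and noise rules", {
  codas <- lapply(c(2, 5, 9, 10, 12), function(k) coda(rep(0.2, k), type = "A"))
  codas[[6]] <- coda(rep(0.2, 4))                    # unlabeled
  codas[[7]] <- coda(rep(0.2, 4), type = "NOISE")
  ds <- coda_dataset(codas)

  # n_clicks = n_icis + 1: max_clicks 10 keeps lengths <= 9
  f1 <- filter_codas(ds, max_clicks = 10)
  expect_equal(sapply(f1$codas, function(cd) length(cd$icis)),
               c(2, 5, 9, 4, 4))
  f2 <- filter_codas(ds, max_icis = 9)
  expect_length(f2, 5)
  f3 <- filter_codas(ds, require_label = "type")
  expect_length(f3, 6)
  f4 <- filter_codas(ds, require_label = "type", drop_labels = "NOISE")
  expect_length(f4, 5)

  # idempotent and order-preserving
  expect_identical(filter_codas(f1, max_clicks = 10)$codas, f1$codas)
  expect_error(filter_codas(ds, require_label = "flavour"))
  expect_length(filter_codas(coda_dataset(list()), max_clicks = 10), 0)
})

test_that("class balancing downsamples every class to the minimum count", {
  ds <- make_labelled_ds(list(EC1 = 15, EC2 = 40))
  bal <- balance_classes(ds, "clan", seed = 3)
  expect_equal(as.vector(table(sapply(bal$codas, `[[`, "clan"))), c(15, 15))
  expect_length(bal, 30)

  same <- make_labelled_ds(list(A = 10, B = 10))
  bal2 <- balance_classes(same, "type", seed = 1)
  expect_length(bal2, 20)
  expect_equal(sort(sapply(bal2$codas, `[[`, "type")),
               sort(sapply(same$codas, `[[`, "type")))

  expect_identical(balance_classes(ds, "clan", seed = 9)$codas,
                   balance_classes(ds, "clan", seed = 9)$codas)
  expect_error(balance_classes(make_labelled_ds(list(A = 5)), "type"),
               "2 classes")
})

test_that("train/test splitting is a disjoint partition with ceiling-sized test", {
  big <- coda_dataset(lapply(seq_len(8032), function(i) coda(rep(0.2, 3))))
  sp <- split_train_test(big, 0.1, seed = 1)
  expect_length(sp$test, 804)
  expect_length(sp$train, 8032 - 804)

  ds <- make_labelled_ds(list(A = 90, B = 10))
  sp2 <- split_train_test(ds, 0.1, seed = 2, stratify_by = "type")
  test_labs <- table(sapply(sp2$test$codas, `[[`, "type"))
  expect_equal(as.vector(test_labs), c(9, 1))
  expect_length(sp2$train, 90)

  # partition property under several seeds
  small <- coda_dataset(lapply(1:17, function(i) coda(i * 0.01)))
  for (seed in 1:3) {
    sp3 <- split_train_test(small, 0.25, seed = seed)
    all_icis <- c(sapply(sp3$train$codas, `[[`, "icis"),
                  sapply(sp3$test$codas, `[[`, "icis"))
    expect_equal(sort(all_icis), sort(sapply(small$codas, `[[`, "icis")))
  }
  expect_error(split_train_test(small, 0.999, seed = 1), "empty")
})

test_that("label encoding maps the sorted vocabulary and round-trips", {
  ds <- make_labelled_ds(list(EC2 = 2, EC1 = 3))
  enc <- encode_labels(ds, "clan")
  expect_equal(enc$mapping, c(EC1 = 0L, EC2 = 1L))
  expect_equal(decode_labels(enc$labels, enc$mapping),
               sapply(ds$codas, `[[`, "clan"))

  one <- make_labelled_ds(list(Z = 4))
  expect_length(encode_labels(one, "type")$mapping, 1)

  mixed <- coda_dataset(list(coda(0.2, type = "A"), coda(0.3)))
  expect_error(encode_labels(mixed, "type"), "missing")
})
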