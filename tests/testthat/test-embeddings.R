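# a corpus where A and B always co-occur (inside windows that also carry
# their own background codes, as diagnosis windows do) while the distractor
# Z never co-occurs with either and keeps to a disjoint background
toy_corpus <- function(n = 300) {
  f_ab <- sprintf("F%02d", 1:4)
  f_z <- sprintf("F%02d", 5:8)
  seqs <- c(
    replicate(n, c("A", "B", sample(f_ab, 2)), simplify = FALSE),
    replicate(n, c("Z", sample(f_z, 3)), simplify = FALSE),
    replicate(n, sample(c(f_ab, f_z), 3), simplify = FALSE))
  w <- data.table(codes = seqs)
  v <- build_vocabulary(w, min_count = 5)
  list(windows = w, vocab = v)
}

test_that("skip-gram brings co-occurring codes together", {
  set.seed(21)
  tc <- toy_corpus()
  emb <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 16,
                              epochs = 10, seed = 3L)
  cos <- function(a, b) {
    va <- emb$matrix[a, ]; vb <- emb$matrix[b, ]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  expect_gt(cos("A", "B"), cos("A", "Z"))
  expect_gt(cos("A", "B"), cos("B", "Z"))
  # co-occurring partner is among the top cosine neighbours
  expect_true("B" %in% utils::head(nearest_codes(emb, "A", 5)$token, 5))
})

test_that("embedding training is deterministic and rejects degenerate corpora", {
  tc <- toy_corpus(50)
  e1 <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 8, epochs = 2,
                             seed = 9L)
  e2 <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 8, epochs = 2,
                             seed = 9L)
  expect_identical(e1$matrix, e2$matrix)
  # an all-short corpus cannot be trained
  short <- replicate(30, "A", simplify = FALSE)
  expect_error(train_code_embedding(short, tc$vocab), ">= 2")
  # provenance guard: no bone-health or oversampled windows
  w <- data.table(codes = list(c("A", "B")), cohort_tag = "bone_health",
                  origin = "native")
  expect_error(train_code_embedding(w, tc$vocab), "pan-therapeutic")
  w2 <- data.table(codes = list(c("A", "B")), cohort_tag = "pan_therapeutic",
                   origin = "oversampled")
  expect_error(train_code_embedding(w2, tc$vocab), "oversampled")
})

test_that("nearest_codes matches a brute-force all-pairs cosine ranking", {
  tc <- toy_corpus(40)
  emb <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 12, epochs = 3,
                              seed = 4L)
  m <- emb$matrix
  for (tok in rownames(m)[1:5]) {
    got <- nearest_codes(emb, tok, 4)
    sims <- apply(m, 1, function(v) {
      sum(v * m[tok, ]) / sqrt(sum(v^2) * sum(m[tok, ]^2))
    })
    sims <- sims[names(sims) != tok]
    want <- names(sort(-sims))[1:4]
    expect_equal(got$token, want)
    expect_false(tok %in% got$token) # never its own neighbour
  }
  expect_equal(nrow(nearest_codes(emb, rownames(m)[1], 0)), 0L)
  expect_error(nearest_codes(emb, "NOPE", 3), "NOPE")
})

test_that("the 2-d projection is complete, finite and reproducible", {
  tc <- toy_corpus(40)
  emb <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 12, epochs = 3,
                              seed = 4L)
  p1 <- project_embedding_2d(emb, seed = 1)
  expect_equal(nrow(p1), length(tc$vocab$tokens))
  expect_true(all(is.finite(p1$x)) && all(is.finite(p1$y)))
  p2 <- project_embedding_2d(emb, seed = 1)
  expect_identical(p1, p2)
})

test_that("distributed bag-of-words summarises whole sequences", {
  tc <- toy_corpus()
  mod <- train_window_embedding(tc$windows$codes, tc$vocab, dim = 24,
                                epochs = 12, seed = 6L)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  s1 <- c("A", "B", "A", "B")
  s3 <- c("Z", "F01", "Z", "F02")
  v1 <- infer_window_vector(mod, s1)
  v2 <- infer_window_vector(mod, s1)       # identical sequence
  v3 <- infer_window_vector(mod, s3)       # disjoint tokens
  expect_equal(length(v1), 24L)
  expect_identical(v1, v2)                 # content-seeded determinism
  expect_gt(cosv(v1, v2), cosv(v1, v3))
  # batch inference equals one-at-a-time inference
  batch <- infer_window_vectors(mod, list(s1, s3))
  expect_equal(batch[1, ], v1)
  expect_equal(batch[2, ], v3)
  # empty sequences give a zero vector with a warning
  expect_warning(v0 <- infer_window_vector(mod, character(0)), "zero vector")
  expect_equal(v0, rep(0, 24))
})

test_that("embed_sequence pads in front, truncates the oldest, keeps the count", {
  tc <- toy_corpus(40)
  emb <- train_code_embedding(tc$windows$codes, tc$vocab, dim = 12, epochs = 2,
                              seed = 2L)
  # 3 tokens into max_len 5: rows 1-2 zero padding, rows 3-5 the vectors
  r <- embed_sequence(c("A", "B", "Z"), emb, max_len = 5)
  expect_equal(dim(r$matrix), c(5L, 12L))
  expect_equal(r$matrix[1:2, ], matrix(0, 2, 12))
  expect_equal(r$matrix[3, ], unname(emb$matrix["A", ]))
  expect_equal(r$matrix[5, ], unname(emb$matrix["Z", ]))
  expect_equal(r$dx_count, 3L)
  # 7 tokens into max_len 5: tokens 3-7 retained
  s7 <- c("F01", "F02", "A", "B", "Z", "F03", "F04")
  r7 <- embed_sequence(s7, emb, max_len = 5)
  expect_equal(r7$matrix[1, ], unname(emb$matrix["A", ]))
  expect_equal(r7$matrix[5, ], unname(emb$matrix["F04", ]))
  expect_equal(r7$dx_count, 7L) # count is pre-truncation
  # out-of-vocabulary tokens map to the zero (unknown) vector
  ro <- embed_sequence(c("A", "NOT-IN-VOCAB"), emb, max_len = 2)
  expect_equal(ro$matrix[2, ], rep(0, 12))
})
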