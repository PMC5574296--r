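# Wavelet decomposition: checked against independently computed reference
# coefficients (PyWavelets, symmetric mode, frozen below) and against the
# perfect-reconstruction property of orthogonal filter banks.

test_that("dwt1 matches frozen reference coefficients (db2)", {
  x <- c(4, 1, 7, 3, 8, 2, 5)
  exp_a1 <- c(4.59619407771, 3.94914646496, 7.42462120246, 6.01040764009, 6.01040764009)
  exp_d1 <- c(1.83711730709, 3.66494342848, 4.14790634163, 0.284203036472, -3.95843765065)
  r <- dwt1(x, "db2")
  expect_equal(r$a, exp_a1, tolerance = 1e-10)
  expect_equal(r$d, exp_d1, tolerance = 1e-10)
  expect_equal(idwt1(r$a, r$d, length(x), "db2"), x, tolerance = 1e-10)
})

test_that("dwt2 matches frozen reference subbands (db3) on an 8x8 image", {
  m <- outer(1:8, 1:8, function(i, j) (i * 13 + j * 7) %% 23)
  exp_a <- matrix(c(24.231800618, 16.2982856968, 18.7415499556, 24.4470292477, 20.3213359369, 18.4915574211, 9.89744910825, 36.5569117671, 19.6817842056, 16.2303870421, 16.5986337349, 31.0479034921, 18.9887770606, 19.069402632, 17.452891391, 24.2566048395, 17.4205805627, 18.513413953, 24.3812682738, 21.8958797798, 21.4486105878, 20.8790746689, 22.8564667693, 20.9906029085, 26.8670501581, 23.1767079528, 30.16586676, 21.8945885045, 24.8480977437, 15.0260733355, 20.4284133913, 6.56366601526, 14.0261543045, 21.9717065736, 23.8456457453, 38.4421937466), 6, 6)
  exp_h <- matrix(c(2.13647627203, 8.18944494595, 4.46898632595, 10.9174274089, -5.51161464876, -10.7674336242, 2.17238522101, -14.2301553784, -10.4316975881, -9.25797228471, 6.32246877132, 9.95657950166, -1.5807589384, -6.36233540729, 3.37457982331, 10.4974717004, -4.82968031568, -10.8648455761, 3.15552442389, 5.41682965047, -11.7921154438, -3.9168165298, 1.73297415489, 9.64638472712, -3.16785602775, 2.88654213725, 11.2606055692, 3.03196021647, -2.84109432016, -5.55248676034, -5.40340465593, -9.12207647343, -9.84284814459, -13.0736774089, 8.16747597643, 11.9272774208), 6, 6)
  exp_v <- matrix(c(-5.9488605877, 7.57215802833, -0.75117099956, -5.23118660012, 2.11790067854, 7.34787911073, -6.88527114646, -2.09236045539, -6.50945066349, -3.93010405468, 7.55704260655, 2.32706417436, -1.73218221421, -10.9426244157, -7.21691675953, 3.16319781296, 8.7804127876, -13.590212386, 0.604785255659, 10.1499306976, -1.22716353593, 8.09879615292, -3.0620941956, 1.84624719786, -1.14494780468, -6.95944861807, -1.59309054227, -4.1263574495, 1.2646777, 2.09019082348, 1.63134348848, 1.3412011995, 8.47850942066, -7.06116223693, -2.2864442183, 0.957804726455), 6, 6)
  exp_d <- matrix(c(3.96984708695, 1.70620388081, -1.98855268932, -7.10707188066, 3.80194222745, 6.65801463692, 4.32119309691, 8.31668524244, 10.5969921086, 5.11251399475, -3.80194222745, -6.65801463692, -5.36635807581, -12.9475712313, -6.52213687589, -0.24737030809, -2.63811886091, 7.57795500412, 9.5985347919, 12.6378783393, 5.11672843338, -9.72195306923, 5.95509489565, 1.06895022437, -4.72100634284, -7.49251766515, -6.04864341348, 2.73245365352, -1.50990939158, 2.13034072177, -4.87752844906, -1.22287685005, 7.80221055711, 11.5520367336, -5.71462692651, -11.1848526767), 6, 6)
  s <- dwt2(m, "db3")
  expect_equal(s$a, exp_a, tolerance = 1e-9)
  expect_equal(s$h, exp_h, tolerance = 1e-9)
  expect_equal(s$v, exp_v, tolerance = 1e-9)
  expect_equal(s$d, exp_d, tolerance = 1e-9)
})

test_that("subband orientation follows edge direction", {
  # horizontal stripes (variation down the rows) excite the h subband
  stripes <- matrix(rep(c(0, 40), each = 2, length.out = 32 * 32), 32, 32)
  s <- dwt2(stripes, "db3")
  expect_gt(sum(s$h^2), 100 * sum(s$v^2))
  s2 <- dwt2(t(stripes), "db3")
  expect_gt(sum(s2$v^2), 100 * sum(s2$h^2))
})

test_that("three-level decomposition yields 9 details and reconstructs", {
  set.seed(5)
  for (dims in list(c(64, 64), c(227, 227), c(61, 45))) {
    x <- matrix(rnorm(prod(dims), sd = 50), dims[1L], dims[2L])
    dc <- dwt3(x)
    expect_length(dc$details, 9L)
    expect_lt(max(abs(idwt3(dc) - x)), 1e-8)
  }
})

test_that("a constant image has no detail energy", {
  dc <- dwt3(matrix(7, 32, 32))
  expect_lt(max(vapply(dc$details, function(d) max(abs(d)), numeric(1))), 1e-10)
  expect_equal(mean(dc$approx) * prod(dim(dc$approx)) / sum(dc$approx), 1,
               tolerance = 1e-12)
})

test_that("detail sizes halve per level and unknown families error", {
  dc <- dwt3(matrix(rnorm(227 * 227), 227), "db3")
  sizes <- vapply(dc$details, nrow, integer(1))
  expect_true(all(sizes[1:3] == sizes[1L]))
  expect_true(all(sizes[4:6] < sizes[1:3]))
  expect_true(all(sizes[7:9] < sizes[4:6]))
  expect_error(dwt3(matrix(0, 16, 16), "sym4"), "unknown wavelet")
  expect_error(dwt1(1:16, "db99"), "unknown wavelet")
})
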