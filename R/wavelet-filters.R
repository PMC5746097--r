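# Filter banks for the supported wavelet families (decomposition /
# reconstruction low/high-pass). Standard published coefficients for the
# Daubechies, symlet, coiflet and biorthogonal-spline families; correctness
# is pinned by the perfect-reconstruction tests.
.wavelet_filters <- list(
  `db1` = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476),
    orthogonal = TRUE
  ),
  `db4` = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764, -0.18703481171909309, -0.027983769416859854, 0.6308807679298589, 0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589, -0.027983769416859854, 0.18703481171909309, 0.030841381835560764, -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589, -0.027983769416859854, -0.18703481171909309, 0.030841381835560764, 0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764, 0.18703481171909309, -0.027983769416859854, -0.6308807679298589, 0.7148465705529157, -0.2303778133088965),
    orthogonal = TRUE
  ),
  `db8` = list(
    dec_lo = c(-0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705, -0.004870352993451574, 0.008746094047405777, 0.013981027917398282, -0.044088253930794755, -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828, -0.2840155429615469, -0.015829105256349306, 0.5853546836542067, 0.6756307362972898, 0.31287159091429995, 0.05441584224310401),
    dec_hi = c(-0.05441584224310401, 0.31287159091429995, -0.6756307362972898, 0.5853546836542067, 0.015829105256349306, -0.2840155429615469, -0.0004724845739132828, 0.12874742662047847, 0.017369301001807547, -0.044088253930794755, -0.013981027917398282, 0.008746094047405777, 0.004870352993451574, -0.00039174037337694705, -0.0006754494064505693, -0.00011747678412476953),
    rec_lo = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898, 0.5853546836542067, -0.015829105256349306, -0.2840155429615469, 0.0004724845739132828, 0.12874742662047847, -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.008746094047405777, -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693, -0.00011747678412476953),
    rec_hi = c(-0.00011747678412476953, -0.0006754494064505693, -0.00039174037337694705, 0.004870352993451574, 0.008746094047405777, -0.013981027917398282, -0.044088253930794755, 0.017369301001807547, 0.12874742662047847, -0.0004724845739132828, -0.2840155429615469, 0.015829105256349306, 0.5853546836542067, -0.6756307362972898, 0.31287159091429995, -0.05441584224310401),
    orthogonal = TRUE
  ),
  `sym3` = list(
    dec_lo = c(0.035226291882100656, -0.08544127388224149, -0.13501102001039084, 0.4598775021193313, 0.8068915093133388, 0.3326705529509569),
    dec_hi = c(-0.3326705529509569, 0.8068915093133388, -0.4598775021193313, -0.13501102001039084, 0.08544127388224149, 0.035226291882100656),
    rec_lo = c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313, -0.13501102001039084, -0.08544127388224149, 0.035226291882100656),
    rec_hi = c(0.035226291882100656, 0.08544127388224149, -0.13501102001039084, -0.4598775021193313, 0.8068915093133388, -0.3326705529509569),
    orthogonal = TRUE
  ),
  `sym7` = list(
    dec_lo = c(0.002681814568257878, -0.0010473848886829163, -0.01263630340325193, 0.03051551316596357, 0.0678926935013727, -0.049552834937127255, 0.017441255086855827, 0.5361019170917628, 0.767764317003164, 0.2886296317515146, -0.14004724044296152, -0.10780823770381774, 0.004010244871533663, 0.010268176708511255),
    dec_hi = c(-0.010268176708511255, 0.004010244871533663, 0.10780823770381774, -0.14004724044296152, -0.2886296317515146, 0.767764317003164, -0.5361019170917628, 0.017441255086855827, 0.049552834937127255, 0.0678926935013727, -0.03051551316596357, -0.01263630340325193, 0.0010473848886829163, 0.002681814568257878),
    rec_lo = c(0.010268176708511255, 0.004010244871533663, -0.10780823770381774, -0.14004724044296152, 0.2886296317515146, 0.767764317003164, 0.5361019170917628, 0.017441255086855827, -0.049552834937127255, 0.0678926935013727, 0.03051551316596357, -0.01263630340325193, -0.0010473848886829163, 0.002681814568257878),
    rec_hi = c(0.002681814568257878, 0.0010473848886829163, -0.01263630340325193, -0.03051551316596357, 0.0678926935013727, 0.049552834937127255, 0.017441255086855827, -0.5361019170917628, 0.767764317003164, -0.2886296317515146, -0.14004724044296152, 0.10780823770381774, 0.004010244871533663, -0.010268176708511255),
    orthogonal = TRUE
  ),
  `coif2` = list(
    dec_lo = c(-0.000720549445520347, -0.0018232088709110323, 0.005611434819368834, 0.02368017194684777, -0.05943441864643109, -0.07648859907828076, 0.4170051844232391, 0.8127236354494135, 0.3861100668227629, -0.0673725547237256, -0.04146493678687178, 0.01638733646320364),
    dec_hi = c(-0.01638733646320364, -0.04146493678687178, 0.0673725547237256, 0.3861100668227629, -0.8127236354494135, 0.4170051844232391, 0.07648859907828076, -0.05943441864643109, -0.02368017194684777, 0.005611434819368834, 0.0018232088709110323, -0.000720549445520347),
    rec_lo = c(0.01638733646320364, -0.04146493678687178, -0.0673725547237256, 0.3861100668227629, 0.8127236354494135, 0.4170051844232391, -0.07648859907828076, -0.05943441864643109, 0.02368017194684777, 0.005611434819368834, -0.0018232088709110323, -0.000720549445520347),
    rec_hi = c(-0.000720549445520347, 0.0018232088709110323, 0.005611434819368834, -0.02368017194684777, -0.05943441864643109, 0.07648859907828076, 0.4170051844232391, -0.8127236354494135, 0.3861100668227629, 0.0673725547237256, -0.04146493678687178, -0.01638733646320364),
    orthogonal = TRUE
  ),
  `coif4` = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.233885431278719e-05, -0.0002599743371222568, -0.0005890202246332165, 0.0012665610789256603, 0.0037514346971460866, -0.0056582838001308835, -0.015211728187697211, 0.02508225333794961, 0.03933442260558915, -0.09622042453595264, -0.06662747236681717, 0.43438603311435653, 0.7822389344242826, 0.41530842700068227, -0.05607731960356926, -0.08126671024919373, 0.02668230466960483, 0.01606894713157503, -0.007346167936268051, -0.001629492425226786, 0.000892313902537003),
    dec_hi = c(-0.000892313902537003, -0.001629492425226786, 0.007346167936268051, 0.01606894713157503, -0.02668230466960483, -0.08126671024919373, 0.05607731960356926, 0.41530842700068227, -0.7822389344242826, 0.43438603311435653, 0.06662747236681717, -0.09622042453595264, -0.03933442260558915, 0.02508225333794961, 0.015211728187697211, -0.0056582838001308835, -0.0037514346971460866, 0.0012665610789256603, 0.0005890202246332165, -0.0002599743371222568, -6.233885431278719e-05, 3.1229861599195265e-05, 3.259647940030751e-06, -1.7849909144933469e-06),
    rec_lo = c(0.000892313902537003, -0.001629492425226786, -0.007346167936268051, 0.01606894713157503, 0.02668230466960483, -0.08126671024919373, -0.05607731960356926, 0.41530842700068227, 0.7822389344242826, 0.43438603311435653, -0.06662747236681717, -0.09622042453595264, 0.03933442260558915, 0.02508225333794961, -0.015211728187697211, -0.0056582838001308835, 0.0037514346971460866, 0.0012665610789256603, -0.0005890202246332165, -0.0002599743371222568, 6.233885431278719e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    rec_hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05, -6.233885431278719e-05, -0.0002599743371222568, 0.0005890202246332165, 0.0012665610789256603, -0.0037514346971460866, -0.0056582838001308835, 0.015211728187697211, 0.02508225333794961, -0.03933442260558915, -0.09622042453595264, 0.06662747236681717, 0.43438603311435653, -0.7822389344242826, 0.41530842700068227, 0.05607731960356926, -0.08126671024919373, -0.02668230466960483, 0.01606894713157503, 0.007346167936268051, -0.001629492425226786, -0.000892313902537003),
    orthogonal = TRUE
  ),
  `bior1.1` = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476),
    orthogonal = FALSE
  ),
  `bior2.4` = list(
    dec_lo = c(0.0, 0.03314563036811941, -0.06629126073623882, -0.1767766952966369, 0.4198446513295126, 0.9943689110435825, 0.4198446513295126, -0.1767766952966369, -0.06629126073623882, 0.03314563036811941),
    dec_hi = c(-0.0, 0.0, -0.0, 0.3535533905932738, -0.7071067811865476, 0.3535533905932738, -0.0, 0.0, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738, 0.0, 0.0, 0.0, 0.0),
    rec_hi = c(0.0, -0.03314563036811941, -0.06629126073623882, 0.1767766952966369, 0.4198446513295126, -0.9943689110435825, 0.4198446513295126, 0.1767766952966369, -0.06629126073623882, -0.03314563036811941),
    orthogonal = FALSE
  ),
  `bior3.3` = list(
    dec_lo = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727, 0.9943689110435825, 0.9943689110435825, -0.15467960838455727, -0.1988737822087165, 0.06629126073623882),
    dec_hi = c(-0.0, 0.0, -0.1767766952966369, 0.5303300858899106, -0.5303300858899106, 0.1767766952966369, -0.0, 0.0),
    rec_lo = c(0.0, 0.0, 0.1767766952966369, 0.5303300858899106, 0.5303300858899106, 0.1767766952966369, 0.0, 0.0),
    rec_hi = c(0.06629126073623882, 0.1988737822087165, -0.15467960838455727, -0.9943689110435825, 0.9943689110435825, 0.15467960838455727, -0.1988737822087165, -0.06629126073623882),
    orthogonal = FALSE
  )
)
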