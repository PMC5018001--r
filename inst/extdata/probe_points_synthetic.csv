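"r","theta","phi","region"
0.000226666666666667,0.20033484232312,2.39996322972865,"interior"
0.00028,0.348166021272961,-1.48325884772228,"interior"
0.000333333333333333,0.451026811796262,0.916704382006372,"interior"
0.000386666666666667,0.535526654314388,-2.96651769544456,"interior"
0.00044,0.609385308030795,-0.566554465715909,"interior"
0.000493333333333333,0.676130509560661,1.83340876401274,"interior"
0.000546666666666667,0.737725968453249,-2.04981331343819,"interior"
6e-04,0.795398830184144,0.350149916290466,"interior"
0.000653333333333333,0.849977565924807,2.75011314601912,"interior"
0.000706666666666667,0.902053623592525,-1.13310893143182,"interior"
0.00076,0.952067636122645,1.26685429829683,"interior"
0.000813333333333333,1.00035921739497,-2.6163677791541,"interior"
0.000866666666666667,1.0471975511966,-0.216404549425437,"interior"
0.00092,1.09280112827594,2.1835586803032,"interior"
0.000973333333333333,1.13735100672501,-1.69966339714773,"interior"
0.00102666666666667,1.18100003032064,0.700299832580928,"interior"
0.00108,1.22387942926773,3.10026306230958,"interior"
0.00113333333333333,1.2661036727795,-0.782959015141348,"interior"
0.00118666666666667,1.30777412388643,1.61700421458729,"interior"
0.00124,1.3489818562981,-2.26621786286364,"interior"
0.00129333333333333,1.38980987554835,0.133745366865018,"interior"
0.00134666666666667,1.43033491208504,2.53370859659367,"interior"
0.0014,1.47062890563334,-1.34951348085726,"interior"
0.00145333333333333,1.51076026834962,1.0504497488714,"interior"
0.00150666666666667,1.55079499322151,-2.83277232857953,"interior"
0.00156,1.59079766036829,-0.432809098850878,"interior"
0.00161333333333333,1.63083238524018,1.96715413087776,"interior"
0.00166666666666667,1.67096374795646,-1.91606794657317,"interior"
0.00172,1.71125774150475,0.483895283155487,"interior"
0.00177333333333333,1.75178277804144,2.88385851288414,"interior"
0.0019235,1.79261079729169,-0.999363564566789,"boundary"
0.0019305,1.83381852970337,1.40059966516187,"boundary"
0.0019375,1.87548898081029,-2.48262241228906,"boundary"
0.0019445,1.91771322432206,-0.0826591825604091,"boundary"
0.0019515,1.96059262326916,2.31730404716823,"boundary"
0.0019585,2.00424164686478,-1.5659180302827,"boundary"
0.0019655,2.04879152531385,0.834045199445956,"boundary"
0.0019725,2.0943951023932,-3.04917687800499,"boundary"
0.0019795,2.14123343619482,-0.649213648276334,"boundary"
0.0019865,2.18952501746715,1.75074958145232,"boundary"
0.00214,2.23953902999727,-2.13247249599861,"bath"
0.00222,2.29161508766499,0.267490733730046,"bath"
0.0023,2.34619382340565,2.6674539634587,"bath"
0.00238,2.40386668513654,-1.21576811399224,"bath"
0.00246,2.46546214402913,1.18419511573643,"bath"
0.00254,2.532207345559,-2.69902696171452,"bath"
0.00262,2.60606599927541,-0.29906373198585,"bath"
0.0027,2.69056584179353,2.10089949774279,"bath"
0.00278,2.79342663231683,-1.78232257970815,"bath"
0.00286,2.94125781126667,0.617640650020515,"bath"
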