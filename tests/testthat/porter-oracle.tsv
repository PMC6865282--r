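word	stem
caresses	caress
ponies	poni
ties	ti
caress	caress
cats	cat
feed	feed
agreed	agre
plastered	plaster
bled	bled
motoring	motor
sing	sing
conflated	conflat
troubled	troubl
sized	size
hopping	hop
tanned	tan
falling	fall
hissing	hiss
fizzed	fizz
failing	fail
filing	file
happy	happi
sky	sky
relational	relat
conditional	condit
rational	ration
valenci	valenc
hesitanci	hesit
digitizer	digit
conformabli	conform
radicalli	radic
differentli	differ
vileli	vile
analogousli	analog
vietnamization	vietnam
predication	predic
operator	oper
feudalism	feudal
decisiveness	decis
hopefulness	hope
callousness	callous
formaliti	formal
sensitiviti	sensit
sensibiliti	sensibl
triplicate	triplic
formative	form
formalize	formal
electriciti	electr
electrical	electr
hopeful	hope
goodness	good
revival	reviv
allowance	allow
inference	infer
airliner	airlin
gyroscopic	gyroscop
adjustable	adjust
defensible	defens
irritant	irrit
replacement	replac
adjustment	adjust
dependent	depend
adoption	adopt
homologou	homolog
communism	commun
activate	activ
angulariti	angular
homologous	homolog
effective	effect
bowdlerize	bowdler
probate	probat
rate	rate
cease	ceas
controll	control
roll	roll
running	run
runner	runner
argument	argument
arguing	argu
argued	argu
flies	fli
dies	di
died	di
agree	agre
owned	own
itemization	item
sensational	sensat
traditional	tradit
reference	refer
colonizer	colon
plotted	plot
stripes	stripe
skies	ski
singing	sing
generalizations	gener
oscillators	oscil
happiness	happi
relationships	relationship
abilities	abil
responsiveness	respons
organization	organ
connections	connect
connection	connect
connective	connect
connected	connect
connecting	connect
university	univers
universities	univers
maximum	maximum
minimum	minimum
presumably	presum
multiply	multipli
provision	provis
crying	cry
string	string
meetings	meet
disappointed	disappoint
disappointing	disappoint
encouragement	encourag
strangely	strang
luxuriously	luxuri
possibly	possibli
probably	probabl
quickly	quickli
slowly	slowli
taking	take
taken	taken
makes	make
making	make
made	made
using	us
used	us
uses	us
user	user
daily	daili
weekly	weekli
monthly	monthli
yearly	yearli
early	earli
eating	eat
drinking	drink
smoking	smoke
injecting	inject
snorting	snort
crushing	crush
chewing	chew
swallowing	swallow
mixing	mix
craving	crave
withdrawal	withdraw
relapse	relaps
recovery	recoveri
addiction	addict
addicted	addict
addictive	addict
dependence	depend
tolerance	toler
overdose	overdos
overdosing	overdos
prescribed	prescrib
prescription	prescript
prescriptions	prescript
refill	refil
refills	refil
pharmacy	pharmaci
pharmacies	pharmaci
doctor	doctor
doctors	doctor
clinics	clinic
hospitals	hospit
emergency	emerg
ambulance	ambul
naloxone	naloxon
methadone	methadon
buprenorphine	buprenorphin
suboxone	suboxon
oxycodone	oxycodon
oxycontin	oxycontin
percocet	percocet
vicodin	vicodin
hydrocodone	hydrocodon
codeine	codein
tramadol	tramadol
fentanyl	fentanyl
morphine	morphin
heroin	heroin
opioids	opioid
opiates	opiat
painkillers	painkil
pills	pill
tablets	tablet
capsules	capsul
doses	dose
dosage	dosag
milligrams	milligram
needles	needl
syringes	syring
injection	inject
prescribing	prescrib
medications	medic
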