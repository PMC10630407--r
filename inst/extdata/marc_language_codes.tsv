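code	name
afr	Afrikaans
alb	Albanian
amh	Amharic
ara	Arabic
arm	Armenian
aze	Azerbaijani
baq	Basque
bel	Belarusian
ben	Bengali
bos	Bosnian
bre	Breton
bul	Bulgarian
bur	Burmese
cat	Catalan
chi	Chinese
cos	Corsican
cze	Czech
dan	Danish
div	Divehi
dut	Dutch
eng	English
epo	Esperanto
est	Estonian
fao	Faroese
fij	Fijian
fin	Finnish
fre	French
gae	Scottish Gaelic
geo	Georgian
ger	German
gla	Gaelic
gle	Irish
glg	Galician
gre	Greek, Modern
grn	Guarani
guj	Gujarati
hau	Hausa
haw	Hawaiian
heb	Hebrew
hin	Hindi
hrv	Croatian
hun	Hungarian
ice	Icelandic
ind	Indonesian
ita	Italian
jav	Javanese
jpn	Japanese
kan	Kannada
kaz	Kazakh
khm	Khmer
kin	Kinyarwanda
kir	Kyrgyz
kor	Korean
kur	Kurdish
lao	Lao
lat	Latin
lav	Latvian
lit	Lithuanian
ltz	Luxembourgish
mac	Macedonian
mal	Malayalam
mao	Maori
mar	Marathi
may	Malay
mlt	Maltese
mon	Mongolian
mul	Multiple languages
nep	Nepali
nor	Norwegian
ori	Oriya
pan	Panjabi
per	Persian
pol	Polish
por	Portuguese
pus	Pushto
que	Quechua
rum	Romanian
rus	Russian
san	Sanskrit
sin	Sinhalese
slo	Slovak
slv	Slovenian
smo	Samoan
som	Somali
spa	Spanish
srp	Serbian
swa	Swahili
swe	Swedish
tag	Tagalog
tam	Tamil
tat	Tatar
tel	Telugu
tha	Thai
tib	Tibetan
tuk	Turkmen
tur	Turkish
ukr	Ukrainian
und	Undetermined
urd	Urdu
uzb	Uzbek
vie	Vietnamese
wel	Welsh
xho	Xhosa
yid	Yiddish
zul	Zulu
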