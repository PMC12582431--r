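el
la
los
las
un
una
unos
unas
y
o
pero
si
de
del
a
al
en
con
por
para
sin
sobre
entre
como
que
cual
quien
cuando
donde
es
son
era
eran
fue
ser
estar
esta
estan
yo
tu
el
ella
ellos
ellas
nosotros
usted
mi
mis
su
sus
nuestro
se
le
les
lo
me
te
nos
no
ni
mas
muy
tambien
hay
ha
han
he
este
esta
estos
estas
ese
esa
eso
aunque
porque
pues
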