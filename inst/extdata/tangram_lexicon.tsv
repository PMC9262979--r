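word	lemma	pos	topic
a	a	determiner	function
above	above	preposition	spatial
abstract	abstract	adjective	shape
against	against	preposition	spatial
agree	agree	verb	action
almost	almost	adverb	function
also	also	adverb	function
am	be	verb	action
an	an	determiner	function
and	and	conjunction	function
angle	angle	verb	action
angled	angled	adjective	shape
any	any	determiner	function
anything	anything	pronoun	function
appear	appear	verb	action
are	be	verb	action
arm	arm	noun	object
around	around	preposition	spatial
arrow	arrow	noun	shape
at	at	preposition	spatial
back	back	noun	object
backward	backward	adverb	function
balance	balance	verb	action
base	base	noun	shape
bat	bat	noun	animal
be	be	verb	action
beak	beak	noun	object
bear	bear	noun	animal
because	because	conjunction	function
been	be	verb	action
behind	behind	preposition	spatial
being	be	verb	action
below	below	preposition	spatial
bend	bend	verb	action
beside	beside	preposition	spatial
between	between	preposition	spatial
big	big	adjective	shape
bird	bird	noun	animal
block	block	noun	shape
boat	boat	noun	object
body	body	noun	object
both	both	determiner	function
bottom	bottom	noun	shape
bridge	bridge	noun	object
but	but	conjunction	function
camel	camel	noun	animal
candle	candle	noun	object
cat	cat	noun	animal
check	check	verb	action
chicken	chicken	noun	animal
corner	corner	noun	shape
crane	crane	noun	animal
crooked	crooked	adjective	shape
curve	curve	verb	action
dance	dance	verb	action
dancer	dancer	noun	object
deer	deer	noun	animal
describe	describe	verb	action
diagonal	diagonal	adjective	shape
diamond	diamond	noun	shape
did	do	verb	action
different	different	adjective	shape
do	do	verb	action
does	do	verb	action
dog	dog	noun	animal
down	down	adverb	function
downward	downward	adverb	function
duck	duck	noun	animal
each	each	determiner	function
ear	ear	noun	object
edge	edge	noun	shape
eight	eight	number	function
end	end	noun	shape
every	every	determiner	function
exactly	exactly	adverb	function
face	face	verb	action
figure	figure	noun	shape
finish	finish	verb	action
first	first	adjective	shape
fish	fish	noun	animal
five	five	number	function
flamingo	flamingo	noun	animal
flat	flat	adjective	shape
flew	fly	verb	action
float	float	verb	action
fly	fly	verb	action
foot	foot	noun	object
form	form	verb	action
forward	forward	adverb	function
four	four	number	function
fox	fox	noun	animal
from	from	preposition	spatial
funny	funny	adjective	shape
geometric	geometric	adjective	shape
giraffe	giraffe	noun	animal
go	go	verb	action
goose	goose	noun	animal
guess	guess	verb	action
had	have	verb	action
half	half	noun	shape
has	have	verb	action
hat	hat	noun	object
have	have	verb	action
he	he	pronoun	function
head	head	noun	object
held	hold	verb	action
here	here	adverb	function
hmm	hmm	interjection	function
hold	hold	verb	action
horizontal	horizontal	adjective	shape
horse	horse	noun	animal
house	house	noun	object
i	i	pronoun	function
if	if	conjunction	function
image	image	noun	shape
in	in	preposition	spatial
into	into	preposition	spatial
is	be	verb	action
it	it	pronoun	function
its	its	determiner	function
itself	itself	pronoun	function
jump	jump	verb	action
just	just	adverb	function
kick	kick	verb	action
kind	kind	adverb	function
kite	kite	noun	object
knee	knee	noun	object
kneel	kneel	verb	action
knew	know	verb	action
know	know	verb	action
lamp	lamp	noun	object
large	large	adjective	shape
last	last	adjective	shape
lean	lean	verb	action
left	left	adverb	function
leg	leg	noun	object
like	like	preposition	spatial
line	line	noun	shape
little	little	adjective	shape
long	long	adjective	shape
look	look	verb	action
lower	lower	adjective	shape
made	make	verb	action
make	make	verb	action
man	man	noun	object
match	match	verb	action
maybe	maybe	adverb	function
me	me	pronoun	function
mean	mean	verb	action
meant	mean	verb	action
middle	middle	noun	shape
mine	mine	pronoun	function
mountain	mountain	noun	object
mouth	mouth	noun	object
move	move	verb	action
my	my	determiner	function
narrow	narrow	adjective	shape
near	near	preposition	spatial
neck	neck	noun	object
next	next	adjective	shape
nine	nine	number	function
no	no	interjection	function
nose	nose	noun	object
not	not	adverb	function
of	of	preposition	spatial
off	off	preposition	spatial
oh	oh	interjection	function
ok	ok	interjection	function
okay	okay	interjection	function
on	on	preposition	spatial
one	one	pronoun	function
ones	one	pronoun	function
onto	onto	preposition	spatial
or	or	conjunction	function
our	our	determiner	function
out	out	adverb	function
outline	outline	noun	shape
over	over	preposition	spatial
page	page	noun	shape
parallelogram	parallelogram	noun	shape
part	part	noun	shape
penguin	penguin	noun	animal
person	person	noun	object
picture	picture	noun	shape
piece	piece	noun	shape
point	point	verb	action
pointy	pointy	adjective	shape
quite	quite	adverb	function
rabbit	rabbit	noun	animal
ran	run	verb	action
reach	reach	verb	action
really	really	adverb	function
remind	remind	verb	action
resemble	resemble	verb	action
right	right	adverb	function
rocket	rocket	noun	object
rooster	rooster	noun	animal
round	round	adjective	shape
run	run	verb	action
runner	runner	noun	object
said	say	verb	action
sailboat	sailboat	noun	object
same	same	adjective	shape
sat	sit	verb	action
saw	see	verb	action
say	say	verb	action
seal	seal	noun	animal
second	second	adjective	shape
see	see	verb	action
seven	seven	number	function
shape	shape	verb	action
sharp	sharp	adjective	shape
she	she	pronoun	function
short	short	adjective	shape
show	show	verb	action
side	side	noun	shape
sideway	sideway	adjective	shape
sideways	sideways	adverb	function
silhouette	silhouette	noun	shape
sit	sit	verb	action
six	six	number	function
slant	slant	verb	action
slanted	slanted	adjective	shape
slope	slope	noun	shape
small	small	adjective	shape
snake	snake	noun	animal
so	so	conjunction	function
some	some	determiner	function
something	something	pronoun	function
sort	sort	adverb	function
square	square	noun	shape
squirrel	squirrel	noun	animal
stand	stand	verb	action
star	star	noun	object
start	start	verb	action
stick	stick	verb	action
stood	stand	verb	action
straight	straight	adjective	shape
strange	strange	adjective	shape
stretch	stretch	verb	action
stuck	stick	verb	action
swan	swan	noun	animal
table	table	noun	object
tail	tail	noun	object
tall	tall	adjective	shape
ten	ten	number	function
that	that	pronoun	function
the	the	determiner	function
their	their	determiner	function
them	them	pronoun	function
then	then	conjunction	function
there	there	adverb	function
these	these	pronoun	function
they	they	pronoun	function
think	think	verb	action
third	third	adjective	shape
this	this	pronoun	function
those	those	pronoun	function
thought	think	verb	action
three	three	number	function
through	through	preposition	spatial
tilt	tilt	verb	action
tilted	tilted	adjective	shape
tip	tip	noun	shape
to	to	preposition	spatial
top	top	noun	shape
touch	touch	verb	action
toward	toward	preposition	spatial
towards	towards	preposition	spatial
tower	tower	noun	object
tree	tree	noun	object
triangle	triangle	noun	shape
turn	turn	verb	action
turtle	turtle	noun	animal
two	two	number	function
uh	uh	interjection	function
um	um	interjection	function
under	under	preposition	spatial
up	up	adverb	function
upper	upper	adjective	shape
upright	upright	adjective	shape
upside	upside	adjective	shape
upward	upward	adverb	function
us	us	pronoun	function
vertical	vertical	adjective	shape
very	very	adverb	function
was	be	verb	action
wave	wave	verb	action
we	we	pronoun	function
weird	weird	adjective	shape
well	well	adverb	function
went	go	verb	action
were	be	verb	action
when	when	conjunction	function
while	while	conjunction	function
whole	whole	adjective	shape
wide	wide	adjective	shape
wing	wing	noun	object
with	with	preposition	spatial
wolf	wolf	noun	animal
woman	woman	noun	object
yeah	yeah	interjection	function
yes	yes	interjection	function
you	you	pronoun	function
your	your	determiner	function
yours	yours	pronoun	function
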