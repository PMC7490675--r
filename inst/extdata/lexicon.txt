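a
an
and
or
but
of
in
on
at
to
for
with
is
are
was
were
be
this
that
it
as
by
from
will
would
could
should
have
has
had
do
does
did
not
no
so
then
there
here
about
into
over
very
just
now
more
most
some
can
may
might
we
our
you
your
they
their
the
crispr
gene
genes
genetic
genetics
editing
edit
edited
genome
genomes
genomic
dna
cas9
cell
cells
science
scientist
scientists
research
researchers
lab
study
studies
technology
tool
tools
therapy
therapies
treatment
treatments
trial
trials
disease
diseases
mutation
mutations
protein
enzyme
sequence
biology
biotech
medicine
clinical
experiment
experiments
human
humans
patient
patients
people
embryo
embryos
baby
babies
born
animal
animals
mouse
mice
pig
pigs
monkey
monkeys
plant
plants
crop
crops
rice
wheat
tomato
bacteria
bacterial
microbe
microbes
virus
viruses
phage
yeast
breakthrough
amazing
hope
hopeful
promising
promise
cure
cures
cured
progress
exciting
incredible
revolutionary
success
successful
benefit
benefits
great
good
better
best
win
wins
save
saves
saving
improve
improves
improved
fear
fears
risk
risks
risky
danger
dangerous
ban
bans
banned
ethics
ethical
unethical
concern
concerns
concerned
worry
worries
worried
alarming
scary
outrage
controversy
controversial
problem
problems
harm
harmful
bad
worse
worst
threat
threats
fail
fails
failed
report
reports
reported
news
announce
announces
announced
publish
publishes
published
paper
papers
explain
explains
explained
review
reviews
update
updates
describe
describes
result
results
data
method
methods
finding
findings
today
new
first
big
next
read
reading
work
working
team
group
talk
talks
look
looks
story
interesting
question
questions
think
thinking
know
knows
world
future
year
years
time
day
week
field
article
blog
video
live
event
meeting
conference
summit
weather
football
soccer
coffee
music
movie
movies
recipe
dinner
holiday
traffic
morning
weekend
game
games
song
songs
cat
cats
dog
dogs
rain
sunny
pizza
beach
party
birthday
shopping
flight
hotel
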