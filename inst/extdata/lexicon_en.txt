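# Small general-English lexicon standing in for WordNet membership lookups.
# One word per line.
about
after
all
and
any
arm
back
bad
best
big
blood
body
bone
book
breath
burn
care
case
chest
child
city
cold
cough
cut
day
days
deep
doctor
dose
drug
each
ear
eat
eye
face
fall
family
fast
fever
find
first
food
foot
form
free
full
general
good
great
group
hand
hard
head
health
heart
heat
help
here
high
home
hospital
hour
house
hurt
information
itch
just
know
last
late
leg
life
like
list
little
long
look
low
make
many
mild
mind
more
most
mouth
move
much
muscle
must
name
neck
need
new
next
night
normal
nose
now
number
nurse
only
open
operation
order
other
over
pain
part
people
pill
place
plan
point
poor
public
pulse
rash
read
real
rest
right
room
safe
said
school
see
set
severe
she
sick
side
sign
site
skin
sleep
slow
small
some
sore
sound
state
stiff
stomach
such
support
swell
system
take
test
than
that
their
them
then
there
these
they
this
throat
time
tired
tooth
top
travel
two
under
university
until
use
used
very
view
visit
warm
water
way
weak
week
well
were
what
when
where
which
will
with
work
world
would
wound
year
years
your
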